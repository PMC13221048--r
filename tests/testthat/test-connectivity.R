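test_that("DPSS tapers are orthonormal and spectrally concentrated", {
  tap <- olfosc:::dpss_tapers(256, 4 / 256, 5)
  G <- crossprod(tap)
  expect_equal(G, diag(5), tolerance = 1e-8)
  ## first taper concentrates its energy inside the half-bandwidth
  ## (|f| <= 4/256 cycles/sample = +-16 bins on the 1024-point padded grid)
  spec <- Mod(fft(c(tap[, 1], rep(0, 768))))^2
  inband <- sum(spec[c(1:17, 1024 - 15:0)])
  expect_gt(inband / sum(spec), 0.98)
})

test_that("white-noise CSD is diagonal-dominant; shared signals cohere", {
  fs <- 128
  set.seed(11)
  x <- matrix(rnorm(60 * 256), 60)
  y <- matrix(rnorm(60 * 256), 60)
  csd <- multitaper_csd(list(x = x, y = y, fs = fs), smoothing_hz = 3)
  coh <- Mod(csd$S[1, 2, ])^2 / (Re(csd$S[1, 1, ]) * Re(csd$S[2, 2, ]))
  expect_lt(mean(coh), 0.05)
  ## diagonals are flat for white noise
  d <- Re(csd$S[1, 1, csd$freqs > 5 & csd$freqs < 60])
  expect_lt(sd(d) / mean(d), 0.25)
  ## common signal -> coherency ~ 1 at its band
  t_ <- (0:255) / fs
  common <- sin(2 * pi * 20 * outer(rep(1, 60), t_))
  csd2 <- multitaper_csd(list(x = x + 5 * common, y = y + 5 * common, fs = fs))
  i20 <- which.min(abs(csd2$freqs - 20))
  coh2 <- Mod(csd2$S[1, 2, i20])^2 / (Re(csd2$S[1, 1, i20]) * Re(csd2$S[2, 2, i20]))
  expect_gt(coh2, 0.95)
})

test_that("window too short for the smoothing bandwidth errors", {
  x <- matrix(rnorm(10 * 32), 10)
  expect_error(multitaper_csd(list(x = x, y = x, fs = 128),
                              smoothing_hz = 1), "too short")
})

test_that("multitaper CSD matches the analytic VAR(2) spectrum", {
  A <- list(matrix(c(0.50, 0.30, 0, 0.50), 2, 2),
            matrix(c(-0.5, 0, 0, -0.5), 2, 2))
  Sigma <- diag(c(1, 0.7))
  fs <- 128
  set.seed(12)
  xs <- replicate(500, simulate_var(A, Sigma, 256), simplify = FALSE)
  csd <- multitaper_csd(list(x = t(sapply(xs, function(m) m[, 1])),
                             y = t(sapply(xs, function(m) m[, 2])), fs = fs),
                        smoothing_hz = 2)
  orc <- var_granger_spectrum(A, Sigma, csd$freqs, fs)
  sel <- csd$freqs > 5 & csd$freqs < 55
  rel <- vapply(which(sel), function(i)
    sqrt(sum(Mod(csd$S[, , i] * fs - orc$S[, , i])^2) /
         sum(Mod(orc$S[, , i])^2)), 0)
  expect_lt(median(rel), 0.05)
})

test_that("Wilson factorization reconstructs the CSD and Granger matches the
           parametric oracle", {
  A <- list(matrix(c(0.50, 0.30, 0, 0.50), 2, 2),
            matrix(c(-0.5, 0, 0, -0.5), 2, 2))
  Sigma <- diag(c(1, 0.7))
  fs <- 128
  set.seed(13)
  xs <- replicate(300, simulate_var(A, Sigma, 512), simplify = FALSE)
  csd <- multitaper_csd(list(x = t(sapply(xs, function(m) m[, 1])),
                             y = t(sapply(xs, function(m) m[, 2])), fs = fs),
                        smoothing_hz = 2)
  fac <- wilson_factorize(csd)
  expect_lt(fac$relerr, 1e-6)
  gc <- spectral_granger(csd)
  orc <- var_granger_spectrum(A, Sigma, csd$freqs, fs)
  pk <- which.max(orc$gc_xy)
  expect_lt(abs(gc$gc_xy[pk] - orc$gc_xy[pk]) / orc$gc_xy[pk], 0.1)
  ## no reverse influence in the generating model
  expect_lt(max(gc$gc_yx[csd$freqs > 5 & csd$freqs < 55]), 0.03)
  ## swapping channels exchanges the directions
  csd_sw <- csd; csd_sw$S <- csd$S[2:1, 2:1, ]
  gc_sw <- spectral_granger(csd_sw)
  expect_equal(gc_sw$gc_xy, gc$gc_yx, tolerance = 0.05)
  expect_equal(gc_sw$gc_yx, gc$gc_xy, tolerance = 0.05)
  ## Geweke non-negativity
  expect_true(all(gc$gc_xy >= 0) && all(gc$gc_yx >= 0))
})

test_that("independent channels give near-zero Granger both ways", {
  fs <- 128
  set.seed(14)
  csd <- multitaper_csd(list(x = matrix(rnorm(100 * 256), 100),
                             y = matrix(rnorm(100 * 256), 100), fs = fs))
  gc <- spectral_granger(csd)
  expect_lt(max(gc$gc_xy), 0.05)
  expect_lt(max(gc$gc_yx), 0.05)
})

test_that("direction contrast recovers injected coupling and validates input", {
  fs <- 256
  cfg <- sim_config(n_participants = 8, n_trials = 20, fs = fs,
                    epoch = c(-0.5, 2.5), seed = 15,
                    effect_spec = list(coupling_effect("OB", "PC",
                                                       c(70, 100), 8, 0.6)))
  d <- generate_dataset(cfg)
  gcl <- lapply(d$trials, function(ts)
    spectral_granger(multitaper_csd(ts, window = c(0, 2))))
  res <- direction_contrast(gcl, c(70, 100))
  expect_gt(res$t, 2)
  expect_lt(res$p, 0.05)
  expect_error(direction_contrast(gcl[1], c(70, 100)), "2 participants")
  expect_error(direction_contrast(gcl, c(300, 400)), "outside")
})
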