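test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_trials = 0), "positive")
  expect_error(sim_config(epoch = c(-1, 1), odor_window = c(0, 2)),
               "contain odor_window")
  expect_error(sim_config(regions = "OB"), "two regions")
  expect_error(sim_config(effect_spec = list(
    power_effect("OB", c(12, 300), c(0, 1), 1)), fs = 512), "Nyquist|fs/2")
  expect_error(sim_config(effect_spec = list(
    power_effect("V1", c(12, 25), c(0, 1), 1))), "unknown region")
  expect_error(sim_config(effect_spec = list(
    power_effect("OB", c(12, 25), c(-3, 1), 1))), "within the epoch")
})

test_that("identical seeds give bit-identical datasets", {
  cfg <- function() sim_config(n_participants = 2, n_trials = 8, fs = 64,
                               epoch = c(-0.5, 2.5), seed = 7,
                               effect_spec = list(
                                 power_effect("OB", c(10, 20), c(0.2, 1), 1, 0.2)))
  d1 <- generate_dataset(cfg())
  d2 <- generate_dataset(cfg())
  expect_identical(d1$behavior, d2$behavior)
  expect_identical(d1$trials[[1]]$data, d2$trials[[1]]$data)
  expect_identical(d1$trials[[2]]$data, d2$trials[[2]]$data)
})

test_that("median-split class means reproduce the reported group ratings", {
  behav <- generate_behavior(sim_config(seed = 11))
  lo <- mean(behav$intensity[behav$intensity_class == "low"])
  hi <- mean(behav$intensity[behav$intensity_class == "high"])
  expect_lt(abs(lo - 3.36), 0.1)
  expect_lt(abs(hi - 6.80), 0.1)
  ## average percent difference between classes as reported
  expect_lt(abs(100 * (hi - lo) / lo - 102), 5)
  ## overlap: the median-split class disagrees with concentration on some
  ## trials (perceived intensity is not concentration)
  expect_gt(mean(behav$intensity_class == "low" &
                 behav$concentration == "High"), 0.05)
})

test_that("rating marginals follow the two-component model", {
  behav <- generate_behavior(sim_config(n_participants = 41, n_trials = 123,
                                        seed = 3))
  x <- behav$intensity
  ## mixture CDF with the generator's calibrated components; clipping puts
  ## atoms at 0 and 10, so compare the interior against the conditional CDF
  comp <- unname(olfosc:::.rating_component_calib)
  mix <- function(q) 0.5 * pnorm(q, comp[1], 2.14) + 0.5 * pnorm(q, comp[2], 1.86)
  p0 <- mix(0); p10 <- 1 - mix(10)
  cond_cdf <- function(q) (mix(q) - p0) / (1 - p0 - p10)
  xi <- x[x > 0 & x < 10]
  ks <- suppressWarnings(stats::ks.test(xi, cond_cdf))
  expect_gt(ks$p.value, 0.001)
})

test_that("injected effects superpose linearly over the background", {
  mk <- function(eff) sim_config(n_participants = 1, n_trials = 6, fs = 64,
                                 epoch = c(-0.5, 2.5), seed = 13,
                                 effect_spec = eff)
  eff <- list(power_effect("OB", c(10, 20), c(0.5, 1.5), 1.5, 0.2))
  d <- generate_dataset(mk(eff), keep_components = TRUE)
  d0 <- generate_dataset(mk(list()))
  ## background equals the no-effect dataset bit-exactly
  expect_identical(d$trials[[1]]$background, d0$trials[[1]]$data)
  ## components account for the difference
  resid <- d$trials[[1]]$data - d$trials[[1]]$background -
    d$trials[[1]]$components[[1]]
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("inject_pac honors identity, modulation and band checks", {
  fs <- 256
  time <- seq(0, 2 - 1 / fs, by = 1 / fs)
  set.seed(2)
  x <- sin(2 * pi * 14 * time) + rnorm(length(time), 0, 0.1)
  expect_identical(inject_pac(x, fs, time, c(12, 16), c(70, 90), 0), x)
  expect_error(inject_pac(x, fs, time, c(12, 30), c(25, 90), 0.5), "disjoint")
  expect_error(inject_pac(x, fs, time, c(12, 16), c(70, 90), 1.5), "0, 1")
  ## modulated output has elevated MI relative to the input
  g <- olfosc:::bandpass_fir(rnorm(length(time)), fs, c(70, 90))
  y0 <- x + g
  y1 <- inject_pac(y0, fs, time, c(12, 16), c(70, 90), 1)
  mi_of <- function(s) {
    ph <- Arg(olfosc:::analytic_signal(olfosc:::bandpass_fir(s, fs, c(12, 16))))
    am <- Mod(olfosc:::analytic_signal(olfosc:::bandpass_fir(s, fs, c(70, 90))))
    tort_mi(ph, am)
  }
  expect_gt(mi_of(y1), 2 * mi_of(y0))
})

test_that("inject_directed_coupling is a pure x-to-y influence", {
  fs <- 128
  set.seed(4)
  x <- rnorm(256); y <- rnorm(256)
  out0 <- inject_directed_coupling(x, y, fs, c(20, 40), lag = 4, gain = 0)
  expect_identical(out0$y, y)
  out <- inject_directed_coupling(x, y, fs, c(20, 40), lag = 4, gain = 0.8)
  expect_identical(out$x, x)
  expect_false(identical(out$y, y))
  expect_error(inject_directed_coupling(x, y, fs, c(20, 40), lag = 0, gain = 1),
               "positive")
})

test_that("inject_burst adds a bounded tapered event", {
  fs <- 128
  time <- seq(-0.5, 2.5 - 1 / fs, by = 1 / fs)
  x <- numeric(length(time))
  expect_identical(inject_burst(x, fs, time, 20, 5, 0.8, 0), x)
  y <- inject_burst(x, fs, time, 20, 5, 0.8, 2)
  idx <- time >= 0.8 & time < 0.8 + 5 / 20
  expect_true(all(y[!idx] == 0))
  ## peak bounded by the amplitude; near it up to taper/carrier sampling
  expect_lte(max(abs(y)), 2)
  expect_gte(max(abs(y)), 1.7)
  expect_error(inject_burst(x, fs, time, 20, 5, 2.4, 1), "past the epoch")
})
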