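test_that("superlet power peaks at the driving frequency", {
  fs <- 512
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  for (f0 in c(10, 25, 40, 80)) {
    tf <- superlet_transform(as_sig(sin(2 * pi * f0 * t), fs),
                             freqs = seq(5, 95, by = 1), frame_rate = 50)
    mid <- tf$frames > 0.5 & tf$frames < 1.5
    peak <- tf$freqs[which.max(rowMeans(tf$power[1, , mid]))]
    expect_lte(abs(peak - f0), 1)
  }
})

test_that("superlet power scales quadratically with amplitude", {
  fs <- 512
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  tf1 <- superlet_transform(as_sig(sin(2 * pi * 40 * t), fs), 40,
                            frame_rate = 50)
  tf2 <- superlet_transform(as_sig(2 * sin(2 * pi * 40 * t), fs), 40,
                            frame_rate = 50)
  mid <- tf1$frames > 0.5 & tf1$frames < 1.5
  ratio <- tf2$power[1, 1, mid] / tf1$power[1, 1, mid]
  expect_equal(mean(ratio), 4, tolerance = 0.01)
  ## a unit-amplitude sinusoid reads out near unit power
  expect_equal(mean(tf1$power[1, 1, mid]), 1, tolerance = 0.01)
})

test_that("order-1 superlet equals an independent Morlet spectrogram", {
  fs <- 200
  set.seed(8)
  for (rep in 1:10) {
    x <- rnorm(300)
    f <- sample(c(10, 15, 22, 30, 45), 1)
    tf <- superlet_transform(as_sig(x, fs), f, order = 1L, frame_rate = fs)
    orc <- oracle_morlet(x, fs, f)
    rel <- max(Mod(tf$coeff[1, 1, ] - orc) / pmax(Mod(orc), 1e-12))
    expect_lt(rel, 1e-10)
  }
})

test_that("frequency above Nyquist is rejected", {
  expect_error(superlet_transform(as_sig(rnorm(100), 100), freqs = c(10, 60)),
               "Nyquist")
})

test_that("time-shift covariance holds away from edges", {
  fs <- 256
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  set.seed(5)
  base <- rnorm(length(t))
  k <- 32L  # shift by 0.125 s = exactly 2 frames at 16 Hz frame rate
  shifted <- c(rep(0, k), base[seq_len(length(t) - k)])
  tfa <- superlet_transform(as_sig(base, fs), c(15, 30), frame_rate = 16)
  tfb <- superlet_transform(as_sig(shifted, fs), c(15, 30), frame_rate = 16)
  nfr <- length(tfa$frames)
  sh <- k / fs * 16  # frames
  inner <- 8:(nfr - 8)
  expect_equal(tfb$power[1, , inner], tfa$power[1, , inner - sh],
               tolerance = 0.02)
})

test_that("band power grows monotonically with injected band amplitude", {
  fs <- 128
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  set.seed(6)
  noise <- rnorm(length(t))
  carrier <- sin(2 * pi * 20 * t)
  bandpow <- sapply(c(0, 0.5, 1, 2), function(a) {
    tf <- superlet_transform(as_sig(noise + a * carrier, fs),
                             freqs = seq(16, 24, by = 2), frame_rate = 16)
    mean(tf$power[1, , tf$frames > 0.3 & tf$frames < 1.7])
  })
  expect_true(all(diff(bandpow) > 0))
})

test_that("coherence is 1 for identical or phase-rotated signals", {
  fs <- 128
  set.seed(9)
  x <- matrix(rnorm(6 * 256), 6)
  sig <- as_sig(x[1, ], fs)
  tfx <- superlet_transform(structure(x, fs = fs, time = attr(sig, "time")),
                            freqs = c(10, 20), frame_rate = 16)
  ## identical
  coh <- coherence_spectrogram(tfx, tfx)
  expect_true(all(abs(coh$coh - 1) < 1e-12))
  ## a fixed phase offset between the channels leaves coherence at 1
  tfy <- tfx
  tfy$coeff <- tfy$coeff * exp(1i * 1.2)
  coh2 <- coherence_spectrogram(tfx, tfy)
  expect_true(all(abs(coh2$coh - 1) < 1e-12))
})

test_that("independent-noise coherence concentrates near 1/n", {
  fs <- 128
  n_tr <- 16
  set.seed(10)
  t_ <- (0:511) / fs
  mk <- function() {
    m <- matrix(rnorm(n_tr * 512), n_tr)
    attr(m, "fs") <- fs; attr(m, "time") <- t_
    superlet_transform(m, freqs = seq(10, 40, by = 10), frame_rate = 8)
  }
  coh <- coherence_spectrogram(mk(), mk())
  inner <- coh$frames > 1 & coh$frames < 3
  expect_equal(mean(coh$coh[, inner]), 1 / n_tr, tolerance = 0.3)
})

test_that("coherence requires at least two trials", {
  fs <- 128
  m <- matrix(rnorm(2 * 256), 2)
  attr(m, "fs") <- fs; attr(m, "time") <- (0:255) / fs
  tf <- superlet_transform(m, freqs = 20, frame_rate = 16)
  expect_error(coherence_spectrogram(tf, tf, trial_subset = 1), "2 trials")
})
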