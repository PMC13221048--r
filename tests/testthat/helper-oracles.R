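## Independent oracles and small fixtures shared across tests.

## Direct time-domain Morlet convolution, written independently of the
## package's FFT path: the oracle for order-1 superlet equivalence.
oracle_morlet <- function(x, fs, f, cycles = 8) {
  s <- cycles / (5 * f)
  half <- ceiling(3 * s * fs)
  tt <- (-half:half) / fs
  env <- exp(-tt^2 / (2 * s^2))
  w <- env * exp(2i * pi * f * tt)
  w <- w * (2 / sum(env))
  n <- length(x)
  pad <- min(half, n - 1L)
  xp <- c(rev(x[2:(pad + 1)]), x, x[n - seq_len(pad)])
  out <- complex(length.out = n)
  for (i in seq_len(n)) {
    lo <- i + pad - half
    seg <- xp[lo:(lo + 2 * half)]
    out[i] <- sum(seg * rev(w))
  }
  out
}

## Closed-form Tort MI of the amplitude profile 1 + d cos(phi) binned into
## n equal phase bins (analytic integral per bin).
mi_analytic <- function(d, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  P <- diff(edges) / (2 * pi) +
    d * (sin(edges[-1]) - sin(edges[-(n_bins + 1)])) / (2 * pi)
  P <- P / sum(P)
  (log(n_bins) + sum(P[P > 0] * log(P[P > 0]))) / log(n_bins)
}

## Plain white-noise trial set (flat spectrum) for burst tests.
white_trial_set <- function(n_trials, fs, epoch = c(-0.5, 2.5), seed = 1) {
  set.seed(seed)
  time <- seq(epoch[1], epoch[2] - 1 / fs, by = 1 / fs)
  dat <- array(stats::rnorm(n_trials * 2 * length(time)),
               c(n_trials, 2, length(time)),
               dimnames = list(NULL, c("OB", "PC"), NULL))
  structure(list(data = dat, time = time, fs = fs, participant = "P01",
                 regions = c("OB", "PC")), class = "trial_set")
}

## Matrix signal with fs/time attributes for superlet_transform.
as_sig <- function(x, fs, t0 = 0) {
  m <- matrix(x, nrow = 1)
  attr(m, "fs") <- fs
  attr(m, "time") <- t0 + (seq_along(x) - 1) / fs
  m
}

## Synthetic per-participant class-wise coherence maps for decode tests.
synthetic_coh_pair <- function(freqs, frames, offset_cells = integer(0),
                               offset = 0, base = 0.2, noise_sd = 0.05) {
  mk <- function(extra) {
    coh <- matrix(pmin(0.95, pmax(0.01, base +
             noise_sd * stats::rnorm(length(freqs) * length(frames)))),
           length(freqs), length(frames))
    coh[offset_cells] <- coh[offset_cells] + extra
    structure(list(coh = pmin(coh, 1), freqs = freqs, frames = frames,
                   n_trials = 20), class = "coherence_map")
  }
  list(low = mk(0), high = mk(offset))
}
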