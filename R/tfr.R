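## Superlet time-frequency decomposition and coherence spectrograms.
##
## The multiplicative superlet estimates power at frequency f as the
## geometric mean, over orders o = 1..O(f), of the magnitude responses of
## Morlet wavelets with o * base_cycles cycles. Longer wavelets sharpen the
## frequency estimate, the base wavelet preserves time resolution; the
## geometric mean keeps the best of both. Complex coefficients (used for
## coherence) are taken from the order-1 base wavelet.

## Morlet wavelet sampled on +-3 Gaussian SDs; s = cycles / (k_sd * f) with
## k_sd = 5 so the Gaussian support spans ~`cycles` periods. Normalized so a
## unit-amplitude sinusoid at f yields |coefficient| ~ 1.
morlet_wavelet <- function(f, cycles, fs) {
  s <- cycles / (5 * f)
  half <- ceiling(3 * s * fs)
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * s^2))
  w <- env * exp(2i * pi * f * t)
  w * (2 / sum(env))
}

#' Adaptive superlet order schedule
#'
#' Linear ramp from order 1 at the lowest analysis frequency to
#' `max_order` at `f_high` (default 100 Hz), rounded up; frequencies beyond
#' `f_high` stay at `max_order`.
#'
#' @param freqs frequency grid (Hz).
#' @param max_order highest superlet order.
#' @param f_low,f_high frequencies mapped to order 1 and `max_order`.
#' @return integer vector of orders, one per frequency.
#' @export
superlet_orders <- function(freqs, max_order = 8, f_low = min(freqs),
                            f_high = 100) {
  o <- ceiling(1 + (max_order - 1) * (freqs - f_low) / (f_high - f_low))
  pmin(pmax(o, 1L), max_order)
}

#' Superlet time-frequency transform
#'
#' Decomposes one region of a trial set into a trials x frequencies x frames
#' map of superlet power plus base-wavelet complex coefficients. Signals are
#' reflection-padded by one longest-wavelet half-length; frames whose
#' longest wavelet support crosses the padding are flagged in
#' `meta$edge` rather than dropped.
#'
#' @param trials a `trial_set` (or plain matrix trials x samples with `fs`
#'   and `time` supplied via attributes of the same names).
#' @param freqs analysis frequencies (Hz), strictly increasing, below
#'   Nyquist.
#' @param base_cycles cycle count of the order-1 wavelet.
#' @param order integer vector of superlet orders per frequency (default
#'   [superlet_orders()]).
#' @param region region label to transform (default first region).
#' @param frame_rate output frame rate in Hz (frames decimated to the
#'   nearest sample).
#' @return object of class `tfr_map`: `coeff` (complex array trials x freqs
#'   x frames), `power`, `freqs`, `frames` (seconds), `fs`, `meta`.
#' @export
superlet_transform <- function(trials, freqs, base_cycles = 8,
                               order = superlet_orders(freqs),
                               region = NULL, frame_rate = 100) {
  if (inherits(trials, "trial_set")) {
    region <- if (is.null(region)) trials$regions[1] else region
    x <- trials$data[, region, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    fs <- trials$fs; time <- trials$time
  } else {
    x <- trials; fs <- attr(trials, "fs"); time <- attr(trials, "time")
  }
  stopifnot(is.numeric(freqs), all(diff(freqs) > 0))
  if (max(freqs) >= fs / 2) stop("analysis frequency at or above Nyquist")
  n_tr <- nrow(x); n_samp <- ncol(x)
  stopifnot(length(time) == n_samp)

  frame_step <- max(1L, round(fs / frame_rate))
  frame_idx <- seq(1L, n_samp, by = frame_step)
  frames <- time[frame_idx]

  ## wavelet bank, padded FFTs shared across trials
  wl <- vector("list", length(freqs))
  for (i in seq_along(freqs))
    wl[[i]] <- lapply(seq_len(order[i]), function(o)
      morlet_wavelet(freqs[i], o * base_cycles, fs))
  pad <- max(vapply(wl, function(ws)
    (length(ws[[length(ws)]]) - 1L) %/% 2L, 0L))
  pad <- min(pad, n_samp - 1L)
  nfft <- next_pow2(n_samp + 2L * pad + max(vapply(wl, function(ws)
    length(ws[[length(ws)]]), 0L)))
  wfft <- lapply(wl, function(ws) lapply(ws, function(w)
    stats::fft(c(w, rep(0, nfft - length(w))))))

  coeff <- array(NA_complex_, dim = c(n_tr, length(freqs), length(frame_idx)))
  power <- array(NA_real_, dim = dim(coeff))
  for (tr in seq_len(n_tr)) {
    sig <- x[tr, ]
    padded <- c(rev(sig[seq_len(pad) + 1L]), sig, sig[n_samp - seq_len(pad)])
    sfft <- stats::fft(c(padded, rep(0, nfft - length(padded))))
    for (i in seq_along(freqs)) {
      gm <- NULL
      for (o in seq_len(order[i])) {
        w <- wl[[i]][[o]]
        half <- (length(w) - 1L) %/% 2L
        conv <- stats::fft(sfft * wfft[[i]][[o]], inverse = TRUE) / nfft
        seg <- conv[(half + pad) + frame_idx]
        mag <- Mod(seg)
        gm <- if (is.null(gm)) log(pmax(mag, 1e-300)) else
          gm + log(pmax(mag, 1e-300))
        if (o == 1L) coeff[tr, i, ] <- seg
      }
      power[tr, i, ] <- exp(2 * gm / order[i])
    }
  }
  ## flag frames whose longest wavelet support crosses the padding
  edge <- matrix(FALSE, length(freqs), length(frame_idx))
  for (i in seq_along(freqs)) {
    half <- (length(wl[[i]][[order[i]]]) - 1L) %/% 2L
    edge[i, ] <- frame_idx - half < 1L | frame_idx + half > n_samp
  }
  structure(list(coeff = coeff, power = power, freqs = freqs, frames = frames,
                 fs = fs, meta = list(base_cycles = base_cycles,
                                      order = order, edge = edge)),
            class = "tfr_map")
}

#' Coherence spectrogram between two time-frequency maps
#'
#' Magnitude-squared coherence per time-frequency cell over a trial subset:
#' `|sum x conj(y)|^2 / (sum |x|^2 * sum |y|^2)`, using the base-wavelet
#' complex coefficients.
#'
#' @param tfr_x,tfr_y `tfr_map` objects on identical frequency/frame grids.
#' @param trial_subset integer indices of trials to pool (default all);
#'   at least 2 (single-trial coherence is identically 1).
#' @return object of class `coherence_map`: `coh` (freqs x frames in
#'   [0, 1]), `freqs`, `frames`, `n_trials`.
#' @export
coherence_spectrogram <- function(tfr_x, tfr_y,
                                  trial_subset = seq_len(dim(tfr_x$coeff)[1])) {
  stopifnot(inherits(tfr_x, "tfr_map"), inherits(tfr_y, "tfr_map"))
  if (!isTRUE(all.equal(tfr_x$freqs, tfr_y$freqs)) ||
      !isTRUE(all.equal(tfr_x$frames, tfr_y$frames)))
    stop("tfr maps must share frequency and frame grids")
  if (length(trial_subset) < 2)
    stop("coherence requires at least 2 trials")
  xs <- tfr_x$coeff[trial_subset, , , drop = FALSE]
  ys <- tfr_y$coeff[trial_subset, , , drop = FALSE]
  cross <- apply(xs * Conj(ys), c(2, 3), sum)
  px <- apply(Mod(xs)^2, c(2, 3), sum)
  py <- apply(Mod(ys)^2, c(2, 3), sum)
  coh <- Mod(cross)^2 / (px * py)
  structure(list(coh = pmin(coh, 1), freqs = tfr_x$freqs,
                 frames = tfr_x$frames, n_trials = length(trial_subset)),
            class = "coherence_map")
}
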