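## Single-trial oscillatory burst detection and burst-rate modeling.
##
## A burst is a run of time frames whose band power exceeds an adaptive
## threshold -- the per-cell mean plus one SD over a block of 10
## consecutive trials -- for at least three cycles of the band's average
## frequency. Burst rates (events/s per frame) are analyzed per frame with
## the same mixed-model machinery as the power maps, Box-Cox transformed
## (rates contain zeros; a +1 shift precedes the transform) and corrected
## along the time axis with 1-D weighted cluster mass.

#' Detect oscillatory bursts in a time-frequency map
#'
#' Thresholds each time-frequency cell at its 10-trial block mean plus
#' `threshold_sd` block SDs; frames where the band's collapsed excess power
#' is positive form candidate runs, retained as burst events when they
#' outlast `min_cycles` cycles of the band's arithmetic mean frequency.
#'
#' @param tfr a `tfr_map`.
#' @param band length-2 band in Hz (beta `c(12, 30)` or gamma
#'   `c(30, 100)`).
#' @param window analysis window in seconds (default 0--2 s after onset).
#' @param block_size trials per threshold block; fewer trials than one
#'   block fall back to a single block with a warning.
#' @param block_mode `"blocked"`: non-overlapping consecutive blocks
#'   threshold their own trials; `"global"`: one block of all trials.
#' @param threshold_sd SD multiplier above the block mean.
#' @param min_cycles minimum duration in cycles of the band mean frequency.
#' @param collapse collapse across the band's frequencies: `"max"`
#'   (default; bursts are narrowband) or `"mean"`.
#' @param exclude_self if `TRUE` (default), each trial is thresholded
#'   against the statistics of the other trials in its block, so a trial's
#'   own bursts cannot inflate its threshold (which would bias onsets late
#'   and track the burst's own envelope); `FALSE` uses the full block
#'   including the scanned trial.
#' @return data.frame of burst events: `trial`, `onset`, `offset`,
#'   `duration`, `duration_cycles`, `peak_freq`, `peak_power`, `band_lo`,
#'   `band_hi`.
#' @export
detect_bursts <- function(tfr, band, window = c(0, 2), block_size = 10,
                          block_mode = c("blocked", "global"),
                          threshold_sd = 1, min_cycles = 3,
                          collapse = c("max", "mean"), exclude_self = TRUE) {
  stopifnot(inherits(tfr, "tfr_map"))
  block_mode <- match.arg(block_mode)
  collapse <- match.arg(collapse)
  fsel <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  tsel <- which(tfr$frames >= window[1] & tfr$frames <= window[2])
  if (!length(fsel) || !length(tsel))
    stop("TFR does not cover the requested band/window")
  pow <- tfr$power[, fsel, tsel, drop = FALSE]
  n_tr <- dim(pow)[1]
  dt <- mean(diff(tfr$frames[tsel]))
  f_mean <- mean(band)
  min_dur <- min_cycles / f_mean

  if (block_mode == "global" || n_tr <= block_size) {
    if (block_mode == "blocked" && n_tr < block_size)
      warning("fewer trials than the block size; using a single block")
    block_of <- rep(1L, n_tr)
  } else {
    block_of <- (seq_len(n_tr) - 1L) %/% block_size + 1L
    ## fold a short remainder into the previous block
    if (sum(block_of == max(block_of)) < block_size)
      block_of[block_of == max(block_of)] <- max(block_of) - 1L
  }

  events <- list()
  for (b in unique(block_of)) {
    trs <- which(block_of == b)
    blk <- pow[trs, , , drop = FALSE]
    m <- length(trs)
    S1 <- apply(blk, c(2, 3), sum)
    S2 <- apply(blk^2, c(2, 3), sum)
    for (tr in trs) {
      x <- pow[tr, , , drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, nrow = length(fsel))
      if (exclude_self && m >= 3) {
        mu <- (S1 - x) / (m - 1)
        va <- pmax((S2 - x^2 - (m - 1) * mu^2) / (m - 2), 0)
      } else {
        mu <- S1 / m
        va <- pmax((S2 - m * mu^2) / (m - 1), 0)
      }
      thr <- mu + threshold_sd * sqrt(va)
      excess <- x - thr
      if (is.null(dim(excess))) excess <- matrix(excess, nrow = length(fsel))
      coll <- if (collapse == "max") apply(excess, 2, max) else
        colMeans(excess)
      active <- coll > 0
      r <- rle(active)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (seg in which(r$values)) {
        i0 <- starts[seg]; i1 <- ends[seg]
        dur <- (i1 - i0 + 1L) * dt
        if (dur <= min_dur) next
        sub <- pow[tr, , i0:i1, drop = TRUE]
        if (is.null(dim(sub))) sub <- matrix(sub, nrow = length(fsel))
        pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        events[[length(events) + 1L]] <- data.frame(
          trial = tr,
          onset = tfr$frames[tsel[i0]],
          offset = tfr$frames[tsel[i1]] + dt,
          duration = dur,
          duration_cycles = dur * f_mean,
          peak_freq = tfr$freqs[fsel[pk[1]]],
          peak_power = max(sub),
          band_lo = band[1], band_hi = band[2])
      }
    }
  }
  if (!length(events))
    return(data.frame(trial = integer(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0),
                      duration_cycles = numeric(0), peak_freq = numeric(0),
                      peak_power = numeric(0), band_lo = numeric(0),
                      band_hi = numeric(0)))
  out <- do.call(rbind, events)
  out[order(out$trial, out$onset), ]
}

#' Burst-rate time series
#'
#' Bins event onsets per frame and per trial, spreads each event over a
#' boxcar of `smoothing` seconds (edge-clipped kernels are renormalized so
#' each event contributes exactly one count), and scales to bursts per
#' second. The series integral over time equals the event count exactly.
#'
#' @param events data.frame from [detect_bursts()].
#' @param n_trials total number of trials (trials without events yield
#'   all-zero rows).
#' @param frames frame time axis in seconds.
#' @param smoothing boxcar width in seconds.
#' @return object of class `burst_rate`: `rate` (trials x frames, bursts/s),
#'   `frames`.
#' @export
burst_rate <- function(events, n_trials, frames, smoothing = 0.1) {
  dt <- mean(diff(frames))
  nF <- length(frames)
  half <- max(0L, round(smoothing / dt / 2))
  rate <- matrix(0, n_trials, nF)
  if (nrow(events)) for (e in seq_len(nrow(events))) {
    j <- which.min(abs(frames - events$onset[e]))
    lo <- max(1L, j - half); hi <- min(nF, j + half)
    rate[events$trial[e], lo:hi] <-
      rate[events$trial[e], lo:hi] + 1 / ((hi - lo + 1L) * dt)
  }
  structure(list(rate = rate, frames = frames, smoothing = smoothing),
            class = "burst_rate")
}

## Box-Cox transform; lambda = 0 is log.
boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

## Profile-likelihood choice of the Box-Cox exponent for y given a fixed-
## effects design (participant entered as dummies for the profiling step).
boxcox_lambda <- function(y, X, group, grid = seq(-1, 2, by = 0.25)) {
  Xf <- cbind(X, stats::model.matrix(~ group)[, -1, drop = FALSE])
  n <- length(y)
  ll <- vapply(grid, function(lam) {
    z <- boxcox_transform(y, lam)
    rss <- sum(stats::lm.fit(Xf, z)$residuals^2)
    -n / 2 * log(rss / n) + (lam - 1) * sum(log(y))
  }, 0)
  grid[which.max(ll)]
}

#' Mixed-model cluster test of burst rates over time
#'
#' Per frame, Box-Cox transforms `rate + shift` (exponent chosen by profile
#' likelihood per frame) and fits the standard random-intercept model; the
#' predictor's t values along time are corrected with a 1-D weighted
#' cluster-mass permutation test (predictor shuffled within participant).
#'
#' @param rates a `burst_rate` object (trials aligned with `behav` rows).
#' @param behav behavioral table.
#' @param predictor,covariates fixed effects as in [fit_lme_map()].
#' @param n_perm,forming_alpha,w cluster-test parameters.
#' @param shift added to rates before the Box-Cox transform (rates contain
#'   zeros).
#' @param seed RNG seed for the permutation schedule.
#' @return a `cluster_result` over the 1 x frames grid.
#' @export
burst_lme <- function(rates, behav, predictor = "intensity",
                      covariates = c("valence", "sniff_amplitude",
                                     "sniff_auc"),
                      n_perm = 1000, forming_alpha = 0.05, w = 2,
                      shift = 1, seed = 1L) {
  stopifnot(inherits(rates, "burst_rate"),
            nrow(rates$rate) == nrow(behav))
  group <- factor(behav$participant)
  X <- lme_design(behav, predictor, covariates)
  nF <- ncol(rates$rate)
  Y <- matrix(NA_real_, nrow(rates$rate), nF)
  for (j in seq_len(nF)) {
    y <- rates$rate[, j] + shift
    if (stats::var(y) == 0)
      stop("constant burst rate at frame ", j, "; model undefined")
    Y[, j] <- boxcox_transform(y, boxcox_lambda(y, X, group))
  }
  rot <- rim_rotate(group)
  fit_map <- function(Xi) {
    fit <- rim_fit(Xi, group, Y, rot = rot)
    tmat <- matrix(fit$t["predictor", ], 1, nF)
    structure(list(t = tmat,
                   p = matrix(2 * stats::pt(-abs(tmat), fit$df), 1, nF),
                   df = fit$df, freqs = NA_real_, frames = rates$frames),
              class = "stat_map")
  }
  observed <- fit_map(X)
  set.seed(seed)
  permuted <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    Xp <- X
    Xp[, "predictor"] <- permute_within(X[, "predictor"], group)
    permuted[[b]] <- fit_map(Xp)
  }
  wcm_test(observed, permuted, forming_alpha, w)
}
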