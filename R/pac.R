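## Phase-amplitude coupling via the Tort modulation index.
##
## The modulation index (MI) is the Kullback-Leibler divergence of the
## phase-binned mean-amplitude distribution from uniform, normalized by
## log(n_bins): 0 for no coupling, 1 when all amplitude concentrates in a
## single phase bin. Trial-level MI in a short window is noisy, so
## inference is by a linear mixed model across trials, mirroring the
## power analyses.

#' Tort modulation index
#'
#' Bins the instantaneous amplitude by instantaneous phase, normalizes the
#' binned means to a distribution P, and returns
#' `KL(P || uniform) / log(n_bins)`.
#'
#' @param phase radians per sample (wrapped to (-pi, pi]).
#' @param amplitude non-negative amplitude per sample, same length.
#' @param n_bins number of phase bins (default 18, i.e. 20 degrees).
#' @return modulation index in [0, 1].
#' @export
tort_mi <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude)) stop("phase and amplitude must have equal length")
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (sum(amplitude) <= 0) stop("total amplitude is zero; MI undefined")
  bin <- pmin(floor((phase + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  means <- rep(0, n_bins)
  agg <- tapply(amplitude, factor(bin, levels = seq_len(n_bins)), mean)
  means[!is.na(agg)] <- agg[!is.na(agg)]
  P <- means / sum(means)
  nz <- P > 0
  (log(n_bins) + sum(P[nz] * log(P[nz]))) / log(n_bins)
}

#' Trial-level phase-amplitude coupling
#'
#' Per trial: zero-phase FIR band-pass of the phase and amplitude bands on
#' the full epoch (filtering inside a 150 ms window would be dominated by
#' edge artifacts), Hilbert analytic phase/amplitude, cropping to the
#' analysis window, then [tort_mi()].
#'
#' @param trials a `trial_set`.
#' @param region_phase,region_amp region labels providing phase and
#'   amplitude (default both OB).
#' @param phase_band,amp_band frequency bands (Hz); defaults beta 12--16
#'   phase, gamma 70--90 amplitude.
#' @param window length-2 analysis window in seconds (default 150 ms
#'   centered on 1.025 s, the period of top-down beta transfer).
#' @param n_bins phase bins for the MI.
#' @return object of class `pac_result`: data.frame with `participant`,
#'   `trial`, `mi`; window/bands in attributes; `flagged_short_window`
#'   attribute set when the window holds fewer than 2 cycles of the lowest
#'   phase frequency.
#' @export
trial_pac <- function(trials, region_phase = NULL, region_amp = NULL,
                      phase_band = c(12, 16), amp_band = c(70, 90),
                      window = c(0.95, 1.10), n_bins = 18) {
  stopifnot(inherits(trials, "trial_set"))
  if (is.null(region_phase)) region_phase <- trials$regions[1]
  if (is.null(region_amp)) region_amp <- trials$regions[1]
  if (window[1] < trials$time[1] || window[2] > trials$time[length(trials$time)])
    stop("analysis window lies outside the epoch")
  win_len <- diff(window)
  if (win_len < 1 / phase_band[1])
    stop("window shorter than one cycle of the lowest phase frequency")
  flagged <- win_len < 2 / phase_band[1]
  idx <- which(trials$time >= window[1] & trials$time < window[2])
  n <- dim(trials$data)[1]
  mi <- numeric(n)
  for (tr in seq_len(n)) {
    ph_sig <- bandpass_fir(trials$data[tr, region_phase, ], trials$fs,
                           phase_band)
    am_sig <- bandpass_fir(trials$data[tr, region_amp, ], trials$fs,
                           amp_band)
    ph <- Arg(analytic_signal(ph_sig))[idx]
    am <- Mod(analytic_signal(am_sig))[idx]
    mi[tr] <- tort_mi(ph, am, n_bins)
  }
  out <- data.frame(participant = trials$participant,
                    trial = seq_len(n), mi = mi)
  attr(out, "phase_band") <- phase_band
  attr(out, "amp_band") <- amp_band
  attr(out, "window") <- window
  attr(out, "flagged_short_window") <- flagged
  class(out) <- c("pac_result", "data.frame")
  out
}

#' Mixed-model analysis of trial-level modulation indices
#'
#' Rank-inverse-normal transforms the per-trial MI and fits the standard
#' mixed model (intensity + valence + sniff amplitude + sniff AUC, random
#' intercept per participant), returning the intensity fixed effect.
#'
#' @param pac `pac_result` rows aligned 1:1 with `behav` rows.
#' @param behav behavioral table.
#' @param predictor fixed effect of interest.
#' @param covariates nuisance fixed effects.
#' @return list with `t`, `p`, `df`, `estimate`, `ci` (Wald 95%), and the
#'   fitted `model`.
#' @export
pac_lme <- function(pac, behav, predictor = "intensity",
                    covariates = c("valence", "sniff_amplitude",
                                   "sniff_auc")) {
  stopifnot(nrow(pac) == nrow(behav))
  dat <- behav
  dat$y <- rank_inverse_normal(pac$mi)
  fml <- stats::as.formula(paste(
    "y ~", paste(c(predictor, covariates), collapse = " + "),
    "+ (1 | participant)"))
  m <- lmerTest::lmer(fml, data = dat, REML = TRUE)
  co <- stats::coef(summary(m))
  est <- co[predictor, "Estimate"]
  se <- co[predictor, "Std. Error"]
  list(t = co[predictor, "t value"], p = co[predictor, "Pr(>|t|)"],
       df = co[predictor, "df"], estimate = est,
       ci = est + c(-1, 1) * stats::qt(0.975, co[predictor, "df"]) * se,
       model = m)
}
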