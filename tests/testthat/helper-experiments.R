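## Shared experiment harnesses for the property-based acceptance checks.

## One null (or effect-bearing) mass-univariate WCM run at desk scale:
## 6 participants x 40 trials, 64 Hz, 3-s epochs, 8x8-cell map over the
## odor window.
wcm_run <- function(seed, n_perm = 200, amp = 0, slope = 0,
                    band = c(12, 25), window = c(0.6, 1.6),
                    freqs = seq(8, 29, by = 3), frame_rate = 4,
                    n_participants = 6, n_trials = 40) {
  eff <- if (amp > 0)
    list(power_effect("OB", band, window, amp, slope)) else list()
  cfg <- sim_config(n_participants = n_participants, n_trials = n_trials,
                    fs = 64, epoch = c(-0.5, 2.5), odor_window = c(0, 2),
                    effect_spec = eff, seed = seed)
  d <- generate_dataset(cfg)
  tf1 <- superlet_transform(d$trials[[1]], freqs, region = "OB",
                            frame_rate = frame_rate)
  pow <- do.call(olfosc:::abind3, c(list(tf1$power),
    lapply(d$trials[-1], function(ts)
      superlet_transform(ts, freqs, region = "OB",
                         frame_rate = frame_rate)$power)))
  mask <- tf1$frames >= 0 & tf1$frames <= 2
  lme_cluster_test(pow, d$behavior, n_perm = n_perm, frame_mask = mask,
                   seed = seed + 7919L, freqs = freqs, frames = tf1$frames)
}

## Smallest corrected p of a cluster result (1 if no clusters formed).
min_corrected_p <- function(cr) {
  if (!length(cr$clusters)) return(1)
  min(vapply(cr$clusters, `[[`, 0, "p_corrected"))
}

## Does the top cluster overlap a band x window rectangle?
top_cluster_overlaps <- function(cr, band, window) {
  ct <- cluster_table(cr)
  if (!nrow(ct)) return(FALSE)
  top <- ct[which.max(ct$mass), ]
  top$freq_hi >= band[1] && top$freq_lo <= band[2] &&
    top$time_hi >= window[1] && top$time_lo <= window[2]
}

## Group-level Granger direction contrast on simulated participants.
granger_contrast_run <- function(seed, gain, n_participants = 20,
                                 n_trials = 30, band = c(70, 100),
                                 lag = 8) {
  eff <- if (gain > 0)
    list(coupling_effect("OB", "PC", band, lag, gain)) else list()
  cfg <- sim_config(n_participants = n_participants, n_trials = n_trials,
                    fs = 256, epoch = c(-0.5, 2.5), odor_window = c(0, 2),
                    effect_spec = eff, seed = seed)
  d <- generate_dataset(cfg)
  gcl <- lapply(d$trials, function(ts)
    spectral_granger(multitaper_csd(ts, window = c(0, 2))))
  direction_contrast(gcl, band)
}

## Trial-level PAC + mixed model on a generated dataset.
pac_lme_run <- function(seed, slope, n_participants = 8, n_trials = 40,
                        depth = 0.5) {
  cfg <- sim_config(n_participants = n_participants, n_trials = n_trials,
                    fs = 256, epoch = c(-0.5, 2.5), odor_window = c(0, 2),
                    effect_spec = list(pac_effect("OB", c(12, 16), c(70, 90),
                                                  c(0.8, 1.2),
                                                  amplitude = 1.5,
                                                  depth = depth,
                                                  slope = slope)),
                    seed = seed)
  d <- generate_dataset(cfg)
  pac <- do.call(rbind, lapply(d$trials, function(ts)
    trial_pac(ts, phase_band = c(12, 16), amp_band = c(70, 90),
              window = c(0.95, 1.10))))
  pac_lme(pac, d$behavior)
}

## Decode feature table on a small synthetic coherence set; `offset` adds a
## class difference inside `offset_cells`.
decode_features_run <- function(seed, n_participants = 6, offset = 0,
                                freqs = seq(10, 34, by = 2),
                                frames = seq(0, 0.2, by = 0.025),
                                offset_cells = integer(0)) {
  set.seed(seed)
  coh <- lapply(seq_len(n_participants), function(p)
    synthetic_coh_pair(freqs, frames, offset_cells = offset_cells,
                       offset = offset))
  build_features(coh, searchlight_grid(freqs, frames,
                                       neighbor_rule = "cells",
                                       min_neighbors = 10))
}
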