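## Dataset container, median split, and the end-to-end pipeline runner.
##
## The on-disk container is a plain-text directory: meta.json with scalar
## attributes, one TSV of signals per participant (rows = trials, columns =
## region x sample, written at full %.17g precision so round trips are
## bit-exact), and behavior.tsv with the per-trial covariates.

#' Within-participant median split of intensity ratings
#'
#' Adds/overwrites `intensity_class`: ratings strictly above the
#' participant's median are `"high"`, ratings below -- and ties at the
#' median -- are `"low"`. Participants whose rating range is below 1.0 are
#' flagged in the `flagged` attribute (too little variability to dichotomize
#' meaningfully); all-identical ratings raise an exclusion log entry via
#' `message`.
#'
#' @param behav behavioral `data.frame` with `participant` and `intensity`.
#' @return the table with `intensity_class` added; flagged participant ids
#'   in `attr(, "flagged")`.
#' @export
median_split <- function(behav) {
  stopifnot(all(c("participant", "intensity") %in% names(behav)))
  flagged <- character(0)
  behav$intensity_class <- NA_character_
  for (p in unique(behav$participant)) {
    i <- behav$participant == p
    x <- behav$intensity[i]
    if (length(unique(x)) < 2) {
      message("participant ", p, " excluded: all-identical intensity ratings")
      flagged <- c(flagged, p)
      next
    }
    if (diff(range(x)) < 1) flagged <- c(flagged, p)
    m <- stats::median(x)
    behav$intensity_class[i] <- ifelse(x > m, "high", "low")
  }
  attr(behav, "flagged") <- flagged
  behav
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a dataset container
#'
#' @param dataset list with `trials` (list of `trial_set`) and `behavior`,
#'   as returned by [generate_dataset()].
#' @param path directory to create.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   dataset list with bit-identical arrays.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ts1 <- dataset$trials[[1]]
  meta <- list(fs = ts1$fs, regions = ts1$regions,
               participants = vapply(dataset$trials, `[[`, "", "participant"),
               n_samples = length(ts1$time), units = "a.u.",
               time_start = ts1$time[1])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(fmt17(ts1$time), file.path(path, "time.tsv"))
  utils::write.table(dataset$behavior, file.path(path, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (ts in dataset$trials) {
    m <- matrix(aperm(ts$data, c(1, 3, 2)), nrow = dim(ts$data)[1])
    con <- file(file.path(path, paste0("signals_", ts$participant, ".tsv")), "w")
    for (r in seq_len(nrow(m))) writeLines(paste(fmt17(m[r, ]), collapse = "\t"), con)
    close(con)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("not a dataset container (missing meta.json)")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (fld in c("fs", "regions", "participants", "n_samples"))
    if (is.null(meta[[fld]])) stop("container schema: missing field '", fld, "'")
  time <- as.numeric(readLines(file.path(path, "time.tsv")))
  behav <- utils::read.table(file.path(path, "behavior.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(c("participant", "intensity", "valence",
                    "sniff_amplitude", "sniff_auc"), names(behav))
  if (length(miss)) stop("behavior table missing column(s): ",
                         paste(miss, collapse = ", "))
  trials <- lapply(meta$participants, function(p) {
    lines <- readLines(file.path(path, paste0("signals_", p, ".tsv")))
    m <- do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
    nr <- length(meta$regions); ns <- meta$n_samples
    dat <- aperm(array(m, dim = c(nrow(m), ns, nr)), c(1, 3, 2))
    dimnames(dat) <- list(NULL, meta$regions, NULL)
    structure(list(data = dat, time = time, fs = meta$fs, participant = p,
                   regions = meta$regions), class = "trial_set")
  })
  n_tr <- sum(vapply(trials, function(t) dim(t$data)[1], 0))
  if (n_tr != nrow(behav))
    stop("container schema: behavioral rows (", nrow(behav),
         ") do not match trial count (", n_tr, ")")
  list(trials = trials, behavior = behav)
}

#' End-to-end pipeline configuration and runner
#'
#' `run_config` bundles every stage's parameters (validated up front);
#' `run_pipeline` executes simulate -> TFR -> mixed-model map ->
#' coherence/decoding -> Granger -> PAC -> bursts according to the stage
#' toggles, writing per-stage TSV reports and a JSON manifest with seeds and
#' file checksums into `out_dir`.
#'
#' @param sim a [sim_config()] (the simulate stage input).
#' @param out_dir output directory.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "tfr", "lme", "coherence", "decode", "granger", "pac",
#'   "bursts")`.
#' @param freqs analysis frequency grid (Hz).
#' @param frame_rate TFR frame rate (Hz).
#' @param n_perm permutations / label shuffles for the cluster tests.
#' @param beta_band,gamma_band bands for the Granger direction contrast.
#' @param pac_phase_band,pac_amp_band,pac_window PAC analysis parameters.
#' @param seed master seed for all stochastic stages.
#' @return `run_config`: a validated config object. `run_pipeline`: a list
#'   of per-stage results, invisibly; reports on disk.
#' @export
run_config <- function(sim = sim_config(n_participants = 6, n_trials = 40,
                                        fs = 128, epoch = c(-0.5, 2.5)),
                       out_dir = tempfile("olfosc_run"),
                       stages = c("simulate", "tfr", "lme", "coherence",
                                  "decode", "granger", "pac", "bursts"),
                       freqs = seq(4, 60, by = 2), frame_rate = 20,
                       n_perm = 200,
                       beta_band = c(12, 30), gamma_band = c(70, 100),
                       pac_phase_band = c(12, 16), pac_amp_band = c(30, 60),
                       pac_window = c(0.95, 1.1), seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  bad <- setdiff(stages, c("simulate", "tfr", "lme", "coherence", "decode",
                           "granger", "pac", "bursts"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (max(freqs) >= sim$fs / 2) stop("analysis frequencies above Nyquist")
  if (n_perm < 1) stop("n_perm must be >= 1")
  structure(list(sim = sim, out_dir = out_dir, stages = stages, freqs = freqs,
                 frame_rate = frame_rate, n_perm = n_perm,
                 beta_band = beta_band, gamma_band = gamma_band,
                 pac_phase_band = pac_phase_band, pac_amp_band = pac_amp_band,
                 pac_window = pac_window, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  need <- function(dep, name) {
    if (is.null(res[[dep]]))
      stop("pipeline stage '", name, "' requires stage '", dep, "'",
           call. = FALSE)
  }

  if ("simulate" %in% st) {
    res$simulate <- stage("simulate", generate_dataset(config$sim))
    utils::write.table(res$simulate$behavior,
                       file.path(config$out_dir, "behavior.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if ("tfr" %in% st) {
    need("simulate", "tfr")
    res$tfr <- stage("tfr", lapply(res$simulate$trials, function(ts)
      lapply(ts$regions[1:2], function(r)
        superlet_transform(ts, config$freqs, region = r,
                           frame_rate = config$frame_rate))))
    for (i in seq_along(res$tfr)) names(res$tfr[[i]]) <-
        res$simulate$trials[[i]]$regions[1:2]
  }
  if ("lme" %in% st) {
    need("tfr", "lme")
    pow <- do.call(abind3, lapply(res$tfr, function(x) x[[1]]$power))
    res$lme <- stage("lme", lme_cluster_test(
      pow, res$simulate$behavior, predictor = "intensity",
      n_perm = config$n_perm, seed = child_seed(config$seed, "lme"),
      freqs = res$tfr[[1]][[1]]$freqs, frames = res$tfr[[1]][[1]]$frames))
    utils::write.table(cluster_table(res$lme),
                       file.path(config$out_dir, "lme_clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if ("coherence" %in% st) {
    need("tfr", "coherence")
    behav <- res$simulate$behavior
    res$coherence <- stage("coherence", lapply(seq_along(res$tfr), function(i) {
      b <- behav[behav$participant ==
                 res$simulate$trials[[i]]$participant, ]
      lapply(c(low = "low", high = "high"), function(cl)
        coherence_spectrogram(res$tfr[[i]][[1]], res$tfr[[i]][[2]],
                              which(b$intensity_class == cl)))
    }))
  }
  if ("decode" %in% st) {
    need("coherence", "decode")
    feats <- stage("decode", build_features(res$coherence))
    res$decode <- stage("decode", shuffle_null_test(
      feats, n_shuffles = config$n_perm,
      seed = child_seed(config$seed, "decode")))
    utils::write.table(res$decode$bin_table,
                       file.path(config$out_dir, "decode_bins.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if ("granger" %in% st) {
    need("simulate", "granger")
    res$granger <- stage("granger", lapply(res$simulate$trials, function(ts)
      spectral_granger(multitaper_csd(ts, window = config$sim$odor_window))))
    gtab <- do.call(rbind, lapply(seq_along(res$granger), function(i) {
      g <- res$granger[[i]]
      data.frame(participant = res$simulate$trials[[i]]$participant,
                 freq = g$freqs, gc_xy = g$gc_xy, gc_yx = g$gc_yx)
    }))
    utils::write.table(gtab, file.path(config$out_dir, "granger.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if ("pac" %in% st) {
    need("simulate", "pac")
    res$pac <- stage("pac", do.call(rbind, lapply(res$simulate$trials,
      function(ts) trial_pac(ts, phase_band = config$pac_phase_band,
                             amp_band = config$pac_amp_band,
                             window = config$pac_window))))
    utils::write.table(res$pac, file.path(config$out_dir, "pac_mi.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if ("bursts" %in% st) {
    need("simulate", "bursts")
    res$bursts <- stage("bursts", do.call(rbind,
      lapply(res$simulate$trials, function(ts) {
        tf <- superlet_transform(ts, config$freqs, base_cycles = 3,
                                 order = rep(1L, length(config$freqs)),
                                 region = ts$regions[1],
                                 frame_rate = config$frame_rate)
        ev <- detect_bursts(tf, band = config$beta_band)
        if (nrow(ev)) ev$participant <- ts$participant
        ev
      })))
    utils::write.table(res$bursts, file.path(config$out_dir, "bursts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("olfosc")),
    seed = config$seed, stages = st,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

## Bind trial-major 3D arrays along the first dimension.
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1], 0)),
                          d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
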