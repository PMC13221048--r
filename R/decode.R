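## Searchlight SVM decoding of the OB-PC coherence spectrogram.
##
## The coherence spectrogram is tiled with overlapping bins (12 Hz x
## 100 ms, 50% stride); marginal bins with too few neighboring bins are
## excluded, leaving an interior searchlight. Each participant contributes
## one trial-averaged coherence map per intensity class, so every bin
## yields one labeled example per participant per class. A linear SVM is
## evaluated leave-one-participant-out; significance comes from a label-
## shuffle Monte-Carlo null with weighted cluster-mass correction over the
## bin grid.

#' Searchlight bin grid over a coherence spectrogram
#'
#' @param freqs,frames axes of the coherence maps.
#' @param bin_hz,bin_s bin extent in Hz and seconds.
#' @param stride_frac stride as a fraction of the bin extent (0.5 =
#'   50% overlap).
#' @param min_neighbors retention threshold.
#' @param neighbor_rule `"bins"`: neighbors are other bins within a
#'   two-bin Chebyshev radius on the bin grid (margin bins fail the rule);
#'   `"cells"`: a bin is retained if it contains at least `min_neighbors`
#'   time-frequency cells.
#' @return object of class `searchlight_grid` with per-bin cell
#'   memberships, neighbor counts and retention flags.
#' @export
searchlight_grid <- function(freqs, frames, bin_hz = 12, bin_s = 0.1,
                             stride_frac = 0.5, min_neighbors = 10,
                             neighbor_rule = c("bins", "cells")) {
  neighbor_rule <- match.arg(neighbor_rule)
  if (diff(range(freqs)) < bin_hz || diff(range(frames)) < bin_s)
    stop("spectrogram smaller than a single searchlight bin")
  f_step <- bin_hz * stride_frac
  t_step <- bin_s * stride_frac
  f0 <- seq(min(freqs), max(freqs) - bin_hz + 1e-9, by = f_step)
  t0 <- seq(min(frames), max(frames) - bin_s + 1e-9, by = t_step)
  nb_f <- length(f0); nb_t <- length(t0)
  bins <- vector("list", nb_f * nb_t)
  k <- 0L
  for (j in seq_len(nb_t)) for (i in seq_len(nb_f)) {
    k <- k + 1L
    cells <- which(outer(freqs >= f0[i] & freqs < f0[i] + bin_hz,
                         frames >= t0[j] & frames < t0[j] + bin_s, "&"))
    bins[[k]] <- list(fi = i, ti = j, f_lo = f0[i], f_hi = f0[i] + bin_hz,
                      t_lo = t0[j], t_hi = t0[j] + bin_s, cells = cells)
  }
  n_neighbors <- integer(length(bins))
  for (k in seq_along(bins)) {
    if (neighbor_rule == "bins") {
      d_f <- abs(vapply(bins, `[[`, 0L, "fi") - bins[[k]]$fi)
      d_t <- abs(vapply(bins, `[[`, 0L, "ti") - bins[[k]]$ti)
      n_neighbors[k] <- sum(pmax(d_f, d_t) <= 2) - 1L
    } else {
      n_neighbors[k] <- length(bins[[k]]$cells)
    }
  }
  retained <- n_neighbors >= min_neighbors &
    vapply(bins, function(b) length(b$cells) > 0, TRUE)
  structure(list(bins = bins, n_neighbors = n_neighbors,
                 retained = retained, nb_f = nb_f, nb_t = nb_t,
                 freqs = freqs, frames = frames,
                 neighbor_rule = neighbor_rule),
            class = "searchlight_grid")
}

#' Build per-bin feature tables from class-wise coherence maps
#'
#' @param coh_list list over participants; each element a list with
#'   components `low` and `high`, the participant's trial-averaged
#'   `coherence_map` per intensity class. Participants missing a class are
#'   excluded with a log message.
#' @param grid a [searchlight_grid()] (defaults to the standard 12 Hz x
#'   100 ms searchlight on the maps' axes).
#' @return object of class `decode_features`: per retained bin a matrix of
#'   examples (2 per participant) x cells, plus `labels`, `participant`,
#'   `grid`.
#' @export
build_features <- function(coh_list, grid = NULL) {
  keep <- vapply(coh_list, function(x)
    !is.null(x$low) && !is.null(x$high), TRUE)
  if (any(!keep))
    message(sum(!keep), " participant(s) excluded: missing a class")
  coh_list <- coh_list[keep]
  if (!length(coh_list)) stop("no participant has both classes")
  m1 <- coh_list[[1]]$low
  if (is.null(grid)) grid <- searchlight_grid(m1$freqs, m1$frames)
  n_p <- length(coh_list)
  labels <- factor(rep(c("low", "high"), n_p), levels = c("low", "high"))
  participant <- rep(seq_len(n_p), each = 2)
  X <- vector("list", length(grid$bins))
  for (k in which(grid$retained)) {
    cells <- grid$bins[[k]]$cells
    X[[k]] <- do.call(rbind, lapply(coh_list, function(x)
      rbind(x$low$coh[cells], x$high$coh[cells])))
  }
  structure(list(X = X, labels = labels, participant = participant,
                 grid = grid), class = "decode_features")
}

## One leave-one-participant-out evaluation of a single bin. Features are
## z-scored with training-fold statistics only; the decision value of the
## linear SVM is evaluated directly from its weight vector.
loo_bin <- function(X, labels, participant, cost = 1) {
  folds <- unique(participant)
  n <- length(labels)
  correct <- logical(n)
  for (p in folds) {
    test <- which(participant == p)
    train <- which(participant != p)
    ytr <- labels[train]
    if (length(unique(ytr)) < 2) stop("degenerate labels in a training fold")
    Xtr <- X[train, , drop = FALSE]
    mu <- colMeans(Xtr)
    Xc <- Xtr - rep(mu, each = nrow(Xtr))
    sd_ <- sqrt(colSums(Xc^2) / (nrow(Xtr) - 1))
    use <- sd_ > 0
    if (!any(use)) {
      ## featureless bin: predict one class throughout; balanced test
      ## pairs then score at exact chance
      correct[test] <- levels(ytr)[1] == as.character(labels[test])
      next
    }
    Ztr <- Xc[, use, drop = FALSE] / rep(sd_[use], each = nrow(Xc))
    Zte <- (X[test, use, drop = FALSE] - rep(mu[use], each = length(test))) /
      rep(sd_[use], each = length(test))
    fit <- e1071::svm(Ztr, ytr, kernel = "linear", cost = cost, scale = FALSE)
    dv <- Zte %*% crossprod(fit$SV, fit$coefs) - fit$rho
    pos <- fit$levels[fit$labels[1]]   # class on the positive decision side
    neg <- setdiff(fit$levels[fit$labels], pos)
    pr <- ifelse(dv > 0, pos, neg)
    correct[test] <- pr == as.character(labels[test])
  }
  truth <- as.character(labels)
  c(accuracy = mean(correct),
    acc_low = mean(correct[truth == "low"]),
    acc_high = mean(correct[truth == "high"]))
}

#' Leave-one-participant-out decoding accuracies
#'
#' Per retained bin, trains a linear SVM (C = 1, features z-scored on the
#' training folds only) on all participants but one and tests on the
#' held-out participant's pair of class examples.
#'
#' @param features a `decode_features` object.
#' @return matrix bins x (accuracy, acc_low, acc_high); non-retained bins
#'   are NA.
#' @export
loo_decode <- function(features) {
  stopifnot(inherits(features, "decode_features"))
  if (length(unique(features$participant)) < 5)
    stop("leave-one-out decoding requires >= 5 participants")
  out <- matrix(NA_real_, length(features$X), 3,
                dimnames = list(NULL, c("accuracy", "acc_low", "acc_high")))
  for (k in which(features$grid$retained))
    out[k, ] <- loo_bin(features$X[[k]], features$labels,
                        features$participant)
  out
}

#' Label-shuffle Monte-Carlo test with cluster correction
#'
#' Re-runs the leave-one-out decoding `n_shuffles` times with class labels
#' permuted within participant (preserving one example per participant per
#' pseudo-class), yielding per-bin one-sided p-values. Accuracies are then
#' z-scored against the shuffle distribution and clusters of adjacent
#' suprathreshold bins are corrected by the weighted cluster-mass
#' statistic.
#'
#' @param features a `decode_features` object.
#' @param n_shuffles number of label shuffles.
#' @param forming_alpha one-sided bin-forming threshold.
#' @param w cluster-mass weight exponent.
#' @param seed RNG seed for the shuffle schedule.
#' @return object of class `decoding_map`: `accuracy` (per bin, with
#'   per-class rates), `p_bin`, `clusters` (with corrected p), `null_acc`
#'   (bins x shuffles), `bin_table` summary.
#' @export
shuffle_null_test <- function(features, n_shuffles = 1000,
                              forming_alpha = 0.05, w = 2, seed = 1L) {
  stopifnot(inherits(features, "decode_features"))
  if (n_shuffles < 100)
    warning("fewer than 100 shuffles: p-values are coarse")
  grid <- features$grid
  obs <- loo_decode(features)
  set.seed(seed)
  n_p <- length(unique(features$participant))
  null_acc <- matrix(NA_real_, length(features$X), n_shuffles)
  ## each shuffle flips or keeps every participant's label pair, so there
  ## are only 2^n_p distinct label patterns: memoize the exact accuracy
  ## map per pattern
  pattern_cache <- new.env(parent = emptyenv())
  for (s in seq_len(n_shuffles)) {
    flip <- sample(c(TRUE, FALSE), n_p, replace = TRUE)
    key <- paste(as.integer(flip), collapse = "")
    if (is.null(pattern_cache[[key]])) {
      lab <- features$labels
      for (p in which(flip)) {
        i <- which(features$participant == p)
        lab[i] <- rev(lab[i])
      }
      shf <- features
      shf$labels <- lab
      pattern_cache[[key]] <- loo_decode(shf)[, "accuracy"]
    }
    null_acc[, s] <- pattern_cache[[key]]
  }
  ret <- grid$retained
  p_bin <- rep(NA_real_, length(features$X))
  p_bin[ret] <- (1 + rowSums(null_acc[ret, , drop = FALSE] >=
                               obs[ret, "accuracy"])) / (n_shuffles + 1)
  mu <- rowMeans(null_acc)
  sd_ <- apply(null_acc, 1, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- NA
  zmap <- matrix(NA_real_, grid$nb_f, grid$nb_t)
  for (k in which(ret)) {
    b <- grid$bins[[k]]
    zmap[b$fi, b$ti] <- (obs[k, "accuracy"] - mu[k]) / sd_[k]
  }
  pmap <- 1 - stats::pnorm(zmap)
  clusters <- find_clusters(zmap, pmap, forming_alpha, w)
  clusters <- Filter(function(cl) cl$sign > 0, clusters)
  null_mass <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    zs <- matrix(NA_real_, grid$nb_f, grid$nb_t)
    for (k in which(ret)) {
      b <- grid$bins[[k]]
      zs[b$fi, b$ti] <- (null_acc[k, s] - mu[k]) / sd_[k]
    }
    cl <- Filter(function(c_) c_$sign > 0,
                 find_clusters(zs, 1 - stats::pnorm(zs), forming_alpha, w))
    null_mass[s] <- if (length(cl)) cl[[1]]$mass else 0
  }
  for (k in seq_along(clusters))
    clusters[[k]]$p_corrected <-
      (1 + sum(null_mass >= clusters[[k]]$mass)) / (n_shuffles + 1)
  bin_cluster_p <- rep(NA_real_, length(features$X))
  for (cl in clusters) for (cell in cl$cells) {
    fi <- (cell - 1L) %% grid$nb_f + 1L
    ti <- (cell - 1L) %/% grid$nb_f + 1L
    hit <- which(vapply(grid$bins, function(b)
      b$fi == fi && b$ti == ti, TRUE))
    bin_cluster_p[hit] <- cl$p_corrected
  }
  bin_table <- do.call(rbind, lapply(seq_along(grid$bins), function(k) {
    b <- grid$bins[[k]]
    data.frame(f_lo = b$f_lo, f_hi = b$f_hi, t_lo = b$t_lo, t_hi = b$t_hi,
               retained = ret[k], accuracy = obs[k, "accuracy"],
               acc_low = obs[k, "acc_low"], acc_high = obs[k, "acc_high"],
               p_bin = p_bin[k], p_cluster = bin_cluster_p[k])
  }))
  structure(list(accuracy = obs, p_bin = p_bin, clusters = clusters,
                 null_acc = null_acc, null_mass = null_mass,
                 bin_table = bin_table, grid = grid),
            class = "decoding_map")
}
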