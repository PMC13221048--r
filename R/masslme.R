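## Mass-univariate linear mixed-effects maps with weighted cluster-mass
## (WCM) Monte-Carlo correction.
##
## Model per time-frequency cell:
##   rank_inverse_normal(power) ~ predictor + valence + sniff_amplitude +
##                                sniff_auc + (1 | participant)
## The fixed-effect t for the predictor of interest forms the statistic map;
## suprathreshold cells (two-sided voxel p below the forming alpha) are
## joined by 8-connectivity and each cluster's mass sum(|t|^w) is referred
## to the permutation distribution of per-map maximum masses, with the
## predictor re-permuted within participant on every permutation.
##
## Two fitting engines: "gls", a profiled-REML random-intercept fitter that
## rotates the data into the grouping structure's eigenbasis and profiles
## the variance ratio on a lambda grid, vectorized over all map cells (this
## is what makes 1,000-permutation refits tractable); and "lmer", the
## lmerTest reference fitter, used for single cells and as the oracle the
## fast engine is validated against.

#' Rank-based inverse normal transform
#'
#' Maps values through Blom scores: ranks (ties averaged) transformed as
#' `qnorm((r - 3/8) / (n + 1/4))`. Invariant under monotone rescaling of
#' the input.
#'
#' @param values numeric vector, at least 3 finite values, not all equal.
#' @return transformed vector (NA where input was NA).
#' @export
rank_inverse_normal <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 3) stop("rank_inverse_normal needs >= 3 finite values")
  x <- values[ok]
  if (diff(range(x)) == 0) stop("rank_inverse_normal undefined for all-equal input")
  r <- rank(x, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  out
}

## Orthonormal rotation for a one-factor random-intercept model.
## Returns Ut (n x n, rows = per-group mean vector then normalized Helmert
## contrasts) and d, the eigenvalues of ZZ' in that basis (group size for
## mean rows, 0 for contrasts).
rim_rotate <- function(group) {
  group <- as.factor(group)
  n <- length(group)
  Ut <- matrix(0, n, n)
  d <- numeric(n)
  row <- 1L
  for (g in levels(group)) {
    idx <- which(group == g)
    m <- length(idx)
    Ut[row, idx] <- 1 / sqrt(m)
    d[row] <- m
    row <- row + 1L
    if (m > 1) {
      H <- stats::contr.helmert(m)
      H <- sweep(H, 2, sqrt(colSums(H^2)), "/")
      Ut[row:(row + m - 2L), idx] <- t(H)
      row <- row + m - 1L
    }
  }
  list(Ut = Ut, d = d, n_groups = nlevels(group))
}

## Vectorized profiled-REML fit of y ~ X + (1|group) for many responses.
## X: n x p (with intercept), Y: n x C. Profiles the variance ratio
## lambda = sigma_b^2 / sigma_e^2 on a log grid shared across cells.
rim_fit <- function(X, group, Y, rot = rim_rotate(group),
                    lambda_grid = c(0, exp(seq(log(1e-3), log(1e3),
                                               length.out = 57)))) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); C <- ncol(Y)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient")
  Xr <- rot$Ut %*% X
  Yr <- rot$Ut %*% Y
  d <- rot$d
  best <- rep(Inf, C); best_i <- rep(1L, C)
  crit_of <- function(lam) {
    w <- 1 / (1 + lam * d)
    Xw <- Xr * w
    G <- crossprod(Xr, Xw)
    R <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    XtWY <- crossprod(Xw, Yr)
    B <- backsolve(R, forwardsolve(t(R), XtWY))
    rss <- colSums(w * Yr^2) - colSums(XtWY * B)
    crit <- (n - p) * log(pmax(rss, 1e-300)) + sum(log(1 + lam * d)) +
      2 * sum(log(diag(R)))
    list(crit = crit, B = B, R = R, rss = rss)
  }
  fits <- vector("list", length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    fit <- crit_of(lambda_grid[i])
    if (is.null(fit)) next
    fits[[i]] <- fit
    upd <- fit$crit < best
    best[upd] <- fit$crit[upd]
    best_i[upd] <- i
  }
  beta <- matrix(NA_real_, p, C, dimnames = list(colnames(X), NULL))
  se <- matrix(NA_real_, p, C, dimnames = list(colnames(X), NULL))
  rss_out <- numeric(C); lam_out <- numeric(C)
  for (i in unique(best_i)) {
    cells <- which(best_i == i)
    fit <- fits[[i]]
    Ginv <- chol2inv(fit$R)
    beta[, cells] <- fit$B[, cells, drop = FALSE]
    sig2 <- fit$rss[cells] / (n - p)
    se[, cells] <- sqrt(outer(diag(Ginv), sig2))
    rss_out[cells] <- fit$rss[cells]
    lam_out[cells] <- lambda_grid[i]
  }
  df <- n - p - (rot$n_groups - 1L)
  list(beta = beta, se = se, t = beta / se, df = df, lambda = lam_out,
       rss = rss_out)
}

## Build the fixed-effect design matrix from the behavioral table.
lme_design <- function(behav, predictor, covariates) {
  pv <- behav[[predictor]]
  if (is.null(pv)) stop("predictor '", predictor, "' not in behavioral table")
  if (is.character(pv) || is.factor(pv)) pv <- as.numeric(factor(pv)) - 1
  if (stats::var(pv) == 0) stop("predictor has zero variance")
  X <- cbind(`(Intercept)` = 1, predictor = pv)
  for (cv in covariates) {
    v <- behav[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not in behavioral table")
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  X
}

#' Mass-univariate mixed-effects map over the time-frequency plane
#'
#' Fits, per time-frequency cell, a random-intercept LME of rank-inverse-
#' normal transformed power on the predictor of interest plus the nuisance
#' covariates, returning the predictor's t map. Cells whose fit is singular
#' are flagged (never silently zeroed); more than 20% flagged cells is an
#' error. A Shapiro-Wilk residual-normality check per cell can be recorded
#' as a QC layer.
#'
#' @param power trials x freqs x frames numeric array (e.g. `tfr$power`),
#'   trials aligned with `behav` rows.
#' @param behav behavioral table (one row per trial).
#' @param predictor `"intensity"` or `"concentration"` (any numeric or
#'   two-level column works).
#' @param covariates nuisance fixed effects.
#' @param engine `"gls"` (fast profiled-REML, used for permutations) or
#'   `"lmer"` (lmerTest reference with Satterthwaite df).
#' @param shapiro if `TRUE`, record per-cell Shapiro-Wilk p of conditional
#'   residuals.
#' @param freqs,frames axis labels carried into the result.
#' @return object of class `stat_map`: matrices `t`, `p`, `beta`, `se`,
#'   scalars/vectors `df`, `flagged`, optional `shapiro_p`.
#' @export
fit_lme_map <- function(power, behav, predictor = "intensity",
                        covariates = c("valence", "sniff_amplitude",
                                       "sniff_auc"),
                        engine = c("gls", "lmer"), shapiro = FALSE,
                        freqs = NULL, frames = NULL) {
  engine <- match.arg(engine)
  if (inherits(power, "tfr_map")) {
    if (is.null(freqs)) freqs <- power$freqs
    if (is.null(frames)) frames <- power$frames
    power <- power$power
  }
  stopifnot(length(dim(power)) == 3, dim(power)[1] == nrow(behav))
  if (length(unique(behav$participant)) < 2)
    stop("at least 2 participants required")
  nf <- dim(power)[2]; nt <- dim(power)[3]
  Y <- apply(matrix(power, nrow = dim(power)[1]), 2, rank_inverse_normal)
  X <- lme_design(behav, predictor, covariates)
  group <- factor(behav$participant)

  if (engine == "gls") {
    rot <- rim_rotate(group)
    fit <- rim_fit(X, group, Y, rot = rot)
    tmat <- matrix(fit$t["predictor", ], nf, nt)
    pmat <- matrix(2 * stats::pt(-abs(fit$t["predictor", ]), fit$df), nf, nt)
    flagged <- !is.finite(tmat)
    df <- fit$df
    beta <- matrix(fit$beta["predictor", ], nf, nt)
    se <- matrix(fit$se["predictor", ], nf, nt)
    shp <- NULL
    if (shapiro) {
      shp <- matrix(NA_real_, nf, nt)
      for (cc in seq_len(ncol(Y))) {
        mres <- Y[, cc] - X %*% fit$beta[, cc]
        lam <- fit$lambda[cc]
        gm <- tapply(mres, group, mean)[group]
        msz <- tapply(mres, group, length)[group]
        bhat <- lam * msz / (1 + lam * msz) * gm
        res <- mres - bhat
        shp[cc] <- tryCatch(stats::shapiro.test(res)$p.value,
                            error = function(e) NA_real_)
      }
    }
  } else {
    tmat <- pmat <- beta <- se <- matrix(NA_real_, nf, nt)
    shp <- if (shapiro) matrix(NA_real_, nf, nt) else NULL
    dfs <- matrix(NA_real_, nf, nt)
    dat <- cbind(as.data.frame(X[, -1, drop = FALSE]),
                 participant = group)
    for (cc in seq_len(ncol(Y))) {
      dat$y <- Y[, cc]
      fml <- stats::as.formula(paste(
        "y ~", paste(setdiff(colnames(X), "(Intercept)"), collapse = " + "),
        "+ (1 | participant)"))
      m <- tryCatch(lmerTest::lmer(fml, data = dat, REML = TRUE),
                    error = function(e) NULL)
      if (is.null(m)) next
      co <- stats::coef(summary(m))
      tmat[cc] <- co["predictor", "t value"]
      pmat[cc] <- co["predictor", "Pr(>|t|)"]
      dfs[cc] <- co["predictor", "df"]
      beta[cc] <- co["predictor", "Estimate"]
      se[cc] <- co["predictor", "Std. Error"]
      if (shapiro)
        shp[cc] <- tryCatch(stats::shapiro.test(stats::residuals(m))$p.value,
                            error = function(e) NA_real_)
    }
    flagged <- !is.finite(tmat)
    df <- dfs
  }
  if (mean(flagged) > 0.2)
    stop("more than 20% of cells failed to fit (", sum(flagged), " cells)")
  structure(list(t = tmat, p = pmat, beta = beta, se = se, df = df,
                 flagged = flagged, shapiro_p = shp, predictor = predictor,
                 freqs = freqs, frames = frames, engine = engine),
            class = "stat_map")
}

## Suprathreshold clusters: cells with voxel p < alpha, joined by
## 8-connectivity separately within each t sign; mass = sum(|t|^w).
find_clusters <- function(tmat, pmat, forming_alpha = 0.05, w = 2) {
  clusters <- list()
  for (sgn in c(1, -1)) {
    mask <- pmat < forming_alpha & sign(tmat) == sgn & is.finite(tmat)
    lab <- label_components_8(mask)
    if (max(lab) == 0) next
    for (k in seq_len(max(lab))) {
      cells <- which(lab == k)
      clusters[[length(clusters) + 1L]] <-
        list(cells = cells, sign = sgn,
             mass = sum(abs(tmat[cells])^w),
             peak_t = tmat[cells][which.max(abs(tmat[cells]))])
    }
  }
  clusters[order(-vapply(clusters, `[[`, 0, "mass"))]
}

#' Weighted cluster-mass permutation test
#'
#' Thresholds the observed statistic map at the two-sided forming alpha,
#' joins suprathreshold cells by 8-connectivity (within t sign), and refers
#' each cluster's mass `sum(|t|^w)` to the distribution of per-permutation
#' maximum masses computed from the permuted maps.
#'
#' @param observed a `stat_map`.
#' @param permuted list of `stat_map`s fitted with the predictor of
#'   interest permuted within participant.
#' @param forming_alpha two-sided voxel cluster-forming threshold.
#' @param w mass weight exponent (mass = sum |t|^w).
#' @return object of class `cluster_result`: `clusters` (list with cells,
#'   mass, peak-cell t, corrected p), `null_masses`, `forming_alpha`, `w`.
#' @export
wcm_test <- function(observed, permuted, forming_alpha = 0.05, w = 2) {
  stopifnot(inherits(observed, "stat_map"))
  n_perm <- length(permuted)
  if (n_perm == 0) stop("wcm_test requires at least one permutation")
  if (n_perm < 100)
    warning("fewer than 100 permutations: corrected p-values are coarse")
  null_masses <- vapply(permuted, function(pm) {
    cl <- find_clusters(pm$t, pm$p, forming_alpha, w)
    if (length(cl)) cl[[1]]$mass else 0
  }, 0)
  clusters <- find_clusters(observed$t, observed$p, forming_alpha, w)
  for (k in seq_along(clusters))
    clusters[[k]]$p_corrected <-
      (1 + sum(null_masses >= clusters[[k]]$mass)) / (n_perm + 1)
  structure(list(clusters = clusters, null_masses = null_masses,
                 forming_alpha = forming_alpha, w = w,
                 freqs = observed$freqs, frames = observed$frames,
                 observed = observed),
            class = "cluster_result")
}

## Permute a vector within the levels of a grouping factor.
permute_within <- function(x, group) {
  out <- x
  for (g in unique(group)) {
    i <- which(group == g)
    out[i] <- x[i[sample.int(length(i))]]
  }
  out
}

#' Mixed-model cluster test over a time-frequency power map
#'
#' Orchestrates the full mass-univariate analysis: fits the observed map,
#' re-fits it `n_perm` times with the predictor of interest shuffled within
#' participant (covariates stay with their trial), and applies the weighted
#' cluster-mass correction. A `frame_mask` restricts the analysis to a
#' subset of frames (e.g. an early 0--500 ms window) without changing the
#' machinery.
#'
#' @inheritParams fit_lme_map
#' @param n_perm number of permutations.
#' @param forming_alpha,w cluster-forming threshold and mass exponent.
#' @param frame_mask optional logical vector over frames.
#' @param seed RNG seed for the permutation schedule.
#' @return a `cluster_result` (see [wcm_test()]).
#' @export
lme_cluster_test <- function(power, behav, predictor = "intensity",
                             covariates = c("valence", "sniff_amplitude",
                                            "sniff_auc"),
                             n_perm = 1000, forming_alpha = 0.05, w = 2,
                             frame_mask = NULL, seed = 1L,
                             freqs = NULL, frames = NULL) {
  if (inherits(power, "tfr_map")) {
    if (is.null(freqs)) freqs <- power$freqs
    if (is.null(frames)) frames <- power$frames
    power <- power$power
  }
  if (!is.null(frame_mask)) {
    power <- power[, , frame_mask, drop = FALSE]
    if (!is.null(frames)) frames <- frames[frame_mask]
  }
  nf <- dim(power)[2]; nt <- dim(power)[3]
  Y <- apply(matrix(power, nrow = dim(power)[1]), 2, rank_inverse_normal)
  group <- factor(behav$participant)
  rot <- rim_rotate(group)
  X <- lme_design(behav, predictor, covariates)
  fit_map <- function(Xi) {
    fit <- rim_fit(Xi, group, Y, rot = rot)
    tmat <- matrix(fit$t["predictor", ], nf, nt)
    structure(list(t = tmat,
                   p = matrix(2 * stats::pt(-abs(tmat), fit$df), nf, nt),
                   df = fit$df, freqs = freqs, frames = frames),
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

#' Flat summary table of a cluster result
#'
#' @param cr a `cluster_result`.
#' @return data.frame with one row per cluster: frequency/time extent,
#'   mass, peak-cell t, corrected p.
#' @export
cluster_table <- function(cr) {
  stopifnot(inherits(cr, "cluster_result"))
  if (!length(cr$clusters))
    return(data.frame(freq_lo = numeric(0), freq_hi = numeric(0),
                      time_lo = numeric(0), time_hi = numeric(0),
                      n_cells = integer(0), mass = numeric(0),
                      peak_t = numeric(0), p_corrected = numeric(0)))
  nf <- length(cr$freqs)
  do.call(rbind, lapply(cr$clusters, function(cl) {
    fr <- (cl$cells - 1L) %% nf + 1L
    tm <- (cl$cells - 1L) %/% nf + 1L
    data.frame(freq_lo = cr$freqs[min(fr)], freq_hi = cr$freqs[max(fr)],
               time_lo = cr$frames[min(tm)], time_hi = cr$frames[max(tm)],
               n_cells = length(cl$cells), mass = cl$mass,
               peak_t = cl$peak_t, p_corrected = cl$p_corrected)
  }))
}
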