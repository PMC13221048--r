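## Frequency-resolved directed connectivity.
##
## Pipeline: DPSS multitaper cross-spectral density over the stimulus
## window -> Wilson iterative spectral matrix factorization S = H Sigma H*
## -> Geweke spectral Granger causality per direction -> group-level
## direction contrast (band-mean gc_xy - gc_yx, one-sample t vs 0), the
## contrast removing variance shared by both directions.

## DPSS (Slepian) tapers via the symmetric tridiagonal formulation:
## diagonal ((N-1-2t)/2)^2 cos(2 pi W), off-diagonal t(N-t)/2. Eigenvectors
## of this matrix are the discrete prolate spheroidal sequences.
dpss_cache <- new.env(parent = emptyenv())
dpss_tapers <- function(n, w, k) {
  key <- paste(n, signif(w, 10), k, sep = "_")
  if (!is.null(dpss_cache[[key]])) return(dpss_cache[[key]])
  t_ <- 0:(n - 1)
  M <- diag(((n - 1 - 2 * t_) / 2)^2 * cos(2 * pi * w))
  off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  M[cbind(1:(n - 1), 2:n)] <- off
  M[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(M, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0 || (abs(sum(tap[, j])) < 1e-9 &&
        tap[which.max(abs(tap[, j])), j] < 0))
      tap[, j] <- -tap[, j]
  }
  dpss_cache[[key]] <- tap
  tap
}

#' Multitaper cross-spectral density of a two-region trial set
#'
#' Computes the trial- and taper-averaged 2x2 cross-spectral matrix over
#' the analysis window using DPSS tapers with the requested half-bandwidth
#' frequency smoothing; the taper count is `2 T W - 1`.
#'
#' @param trials a `trial_set`, or a list `list(x = , y = , fs = )` with
#'   trials x samples matrices (used by oracle simulations).
#' @param window length-2 analysis window in seconds (default the 0--2 s
#'   stimulus period).
#' @param smoothing_hz spectral smoothing half-bandwidth W in Hz.
#' @param regions two region labels (default the first two).
#' @return object of class `csd`: `S` (2 x 2 x nfreq complex, Hermitian
#'   PSD), `freqs`, `fs`, `n_tapers`, `smoothing_hz`.
#' @export
multitaper_csd <- function(trials, window = c(0, 2), smoothing_hz = 3,
                           regions = NULL) {
  if (inherits(trials, "trial_set")) {
    if (is.null(regions)) regions <- trials$regions[1:2]
    idx <- which(trials$time >= window[1] & trials$time < window[2])
    x <- trials$data[, regions[1], idx, drop = TRUE]
    y <- trials$data[, regions[2], idx, drop = TRUE]
    if (is.null(dim(x))) { x <- matrix(x, 1); y <- matrix(y, 1) }
    fs <- trials$fs
  } else {
    x <- trials$x; y <- trials$y; fs <- trials$fs
    if (is.null(dim(x))) { x <- matrix(x, 1); y <- matrix(y, 1) }
  }
  n <- ncol(x)
  T_ <- n / fs
  k <- floor(2 * T_ * smoothing_hz - 1)
  if (k < 1) stop("window too short for the requested smoothing bandwidth")
  tap <- dpss_tapers(n, smoothing_hz / fs, k)  # half-bandwidth in cycles/sample
  nf <- floor(n / 2) + 1L
  freqs <- (seq_len(nf) - 1) / T_
  S <- array(0 + 0i, dim = c(2, 2, nf))
  for (tr in seq_len(nrow(x))) {
    xc <- x[tr, ] - mean(x[tr, ])
    yc <- y[tr, ] - mean(y[tr, ])
    for (j in seq_len(k)) {
      X <- stats::fft(tap[, j] * xc)[seq_len(nf)]
      Y <- stats::fft(tap[, j] * yc)[seq_len(nf)]
      S[1, 1, ] <- S[1, 1, ] + X * Conj(X)
      S[2, 2, ] <- S[2, 2, ] + Y * Conj(Y)
      S[1, 2, ] <- S[1, 2, ] + X * Conj(Y)
      S[2, 1, ] <- S[2, 1, ] + Y * Conj(X)
    }
  }
  S <- S / (nrow(x) * k * fs)
  structure(list(S = S, freqs = freqs, fs = fs, n_tapers = k,
                 smoothing_hz = smoothing_hz), class = "csd")
}

## Causal-part ("plus") operator of Wilson's algorithm: transform to the
## lag domain, keep positive lags plus the upper-triangular half of the
## zero lag, transform back. g: 2 x 2 x M over the full (two-sided) grid.
plus_operator <- function(g) {
  M <- dim(g)[3]
  gam <- array(0 + 0i, dim = dim(g))
  for (i in 1:2) for (j in 1:2)
    gam[i, j, ] <- stats::fft(g[i, j, ], inverse = TRUE) / M
  ## zero lag: g0 = B + B* with B upper triangular -> halve the diagonal,
  ## keep the full upper off-diagonal, drop the lower
  ## self-paired lags (0 and, for even M, Nyquist M/2): halve the diagonal,
  ## keep the full upper off-diagonal, drop the lower
  for (m0 in unique(c(1L, M %/% 2 + 1L))) {
    gam[1, 1, m0] <- 0.5 * gam[1, 1, m0]
    gam[2, 2, m0] <- 0.5 * gam[2, 2, m0]
    gam[2, 1, m0] <- 0
  }
  keep <- seq_len(M %/% 2 + 1L)
  gam[, , setdiff(seq_len(M), keep)] <- 0
  gp <- array(0 + 0i, dim = dim(g))
  for (i in 1:2) for (j in 1:2)
    gp[i, j, ] <- stats::fft(gam[i, j, ])
  gp
}

#' Wilson spectral matrix factorization
#'
#' Factorizes a one-sided cross-spectral density S(f) into
#' `S = H Sigma H*` with minimum-phase transfer function H and real
#' innovation covariance Sigma, by Wilson's iterative algorithm. A small
#' diagonal loading (`1e-8 * mean trace`) guards positive definiteness.
#'
#' @param csd a `csd` object (uniform frequency grid from 0 to Nyquist).
#' @param max_iter maximum iterations.
#' @param tol relative Frobenius tolerance of the reconstruction.
#' @return list with `H` (2 x 2 x nfreq), `Sigma` (2 x 2), `relerr`,
#'   `n_iter`.
#' @export
wilson_factorize <- function(csd, max_iter = 200, tol = 1e-9) {
  stopifnot(inherits(csd, "csd"))
  S1 <- csd$S
  nf <- dim(S1)[3]
  load <- 1e-8 * mean(Re(S1[1, 1, ] + S1[2, 2, ]))
  S1[1, 1, ] <- S1[1, 1, ] + load
  S1[2, 2, ] <- S1[2, 2, ] + load
  M <- 2L * (nf - 1L)
  S <- array(0 + 0i, dim = c(2, 2, M))
  S[, , seq_len(nf)] <- S1
  for (m in (nf + 1L):M) S[, , m] <- Conj(S1[, , M - m + 2L])
  A <- matrix(0, 2, 2)
  for (m in seq_len(M)) A <- A + Re(S[, , m])
  A <- A / M
  psi0 <- t(chol(A))                     # lower, psi0 %*% t(psi0) = A
  psi <- array(0 + 0i, dim = c(2, 2, M))
  for (m in seq_len(M)) psi[, , m] <- psi0
  I2 <- diag(2)
  relerr <- Inf
  for (it in seq_len(max_iter)) {
    g <- array(0 + 0i, dim = c(2, 2, M))
    for (m in seq_len(M)) {
      pinv <- solve(psi[, , m])
      g[, , m] <- pinv %*% S[, , m] %*% Conj(t(pinv)) + I2
    }
    gp <- plus_operator(g)
    psinew <- array(0 + 0i, dim = c(2, 2, M))
    for (m in seq_len(M)) psinew[, , m] <- psi[, , m] %*% gp[, , m]
    num <- 0; den <- 0
    for (m in seq_len(nf)) {
      R <- psinew[, , m] %*% Conj(t(psinew[, , m])) - S[, , m]
      num <- num + sum(Mod(R)^2)
      den <- den + sum(Mod(S[, , m])^2)
    }
    relerr <- sqrt(num / den)
    psi <- psinew
    if (relerr < tol) break
  }
  if (relerr > 1e-6)
    stop(sprintf(
      "Wilson factorization did not converge (relative residual %.3g)",
      relerr))
  ## zero-lag coefficient A0: psi's lag-0 term
  A0 <- matrix(0 + 0i, 2, 2)
  for (i in 1:2) for (j in 1:2)
    A0[i, j] <- sum(psi[i, j, ]) / M
  A0 <- Re(A0)
  Sigma <- A0 %*% t(A0)
  H <- array(0 + 0i, dim = c(2, 2, nf))
  A0inv <- solve(A0)
  for (m in seq_len(nf)) H[, , m] <- psi[, , m] %*% A0inv
  list(H = H, Sigma = Sigma, relerr = relerr, n_iter = it,
       psi = psi[, , seq_len(nf)])
}

## Geweke directional terms from S, H, Sigma on a one-sided grid.
geweke_gc <- function(S, H, Sigma) {
  nf <- dim(S)[3]
  S11 <- pmax(Re(S[1, 1, ]), 1e-300)
  S22 <- pmax(Re(S[2, 2, ]), 1e-300)
  ## 2 -> 1: remove the part of S11 carried by channel 2's innovations
  s2c <- Sigma[2, 2] - Sigma[1, 2]^2 / Sigma[1, 1]
  s1c <- Sigma[1, 1] - Sigma[1, 2]^2 / Sigma[2, 2]
  gc_yx <- log(S11 / pmax(S11 - s2c * Mod(H[1, 2, ])^2, 1e-300))
  gc_xy <- log(S22 / pmax(S22 - s1c * Mod(H[2, 1, ])^2, 1e-300))
  list(gc_xy = pmax(gc_xy, 0), gc_yx = pmax(gc_yx, 0))
}

#' Nonparametric spectral Granger causality
#'
#' Computes Geweke's frequency-resolved directional influence in both
#' directions from a cross-spectral density, via Wilson factorization:
#' `gc_yx(f) = ln(Sxx / (Sxx - (Sigma_yy - Sigma_xy^2 / Sigma_xx) |Hxy|^2))`
#' and symmetrically for x to y.
#'
#' @param csd a `csd` object.
#' @param ... passed to [wilson_factorize()].
#' @return object of class `gc_spectrum`: `gc_xy`, `gc_yx` (non-negative,
#'   per frequency), `freqs`, `factorization_relerr`.
#' @export
spectral_granger <- function(csd, ...) {
  fac <- wilson_factorize(csd, ...)
  gc <- geweke_gc(csd$S, fac$H, fac$Sigma)
  structure(list(gc_xy = gc$gc_xy, gc_yx = gc$gc_yx, freqs = csd$freqs,
                 factorization_relerr = fac$relerr, Sigma = fac$Sigma),
            class = "gc_spectrum")
}

#' Group-level direction contrast
#'
#' Per participant, the band-averaged `gc_xy - gc_yx`; across participants
#' a two-tailed one-sample t test against zero. Subtracting the two
#' directions removes variance shared by both (overall coupling strength),
#' isolating directionality.
#'
#' @param gc_list list of `gc_spectrum`, one per participant.
#' @param band length-2 frequency band in Hz.
#' @return list with `t`, `p`, `ci` (95%), `contrasts` (per participant),
#'   `band`.
#' @export
direction_contrast <- function(gc_list, band) {
  if (length(gc_list) < 2) stop("direction contrast requires >= 2 participants")
  contrasts <- vapply(gc_list, function(g) {
    sel <- g$freqs >= band[1] & g$freqs <= band[2]
    if (!any(sel)) stop("band outside the spectrum's frequency range")
    mean(g$gc_xy[sel] - g$gc_yx[sel])
  }, 0)
  tt <- stats::t.test(contrasts)
  list(t = unname(tt$statistic), p = tt$p.value,
       ci = unname(tt$conf.int), contrasts = contrasts, band = band)
}

#' Simulate a bivariate VAR process
#'
#' @param A list of 2x2 lag coefficient matrices.
#' @param Sigma 2x2 innovation covariance.
#' @param n samples to return (after `burn` burn-in samples).
#' @param burn burn-in length.
#' @return n x 2 matrix.
#' @export
simulate_var <- function(A, Sigma, n, burn = 200) {
  p <- length(A)
  L <- t(chol(Sigma))
  ntot <- n + burn
  x <- matrix(0, ntot, 2)
  for (t_ in (p + 1):ntot) {
    e <- L %*% stats::rnorm(2)
    acc <- e
    for (k in seq_len(p)) acc <- acc + A[[k]] %*% x[t_ - k, ]
    x[t_, ] <- acc
  }
  x[(burn + 1):ntot, , drop = FALSE]
}

#' Analytic Geweke spectrum of a known VAR process
#'
#' Closed-form reference: `H(f) = (I - sum_k A_k e^(-2 pi i f k / fs))^-1`,
#' `S = H Sigma H*`, then the same Geweke decomposition as the
#' nonparametric route. Serves as the independent oracle for
#' [spectral_granger()] on simulated processes.
#'
#' @inheritParams simulate_var
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (Hz).
#' @return list with `gc_xy`, `gc_yx`, `S`, `H`, `freqs`.
#' @export
var_granger_spectrum <- function(A, Sigma, freqs, fs) {
  nf <- length(freqs)
  S <- array(0 + 0i, dim = c(2, 2, nf))
  H <- array(0 + 0i, dim = c(2, 2, nf))
  I2 <- diag(2)
  for (m in seq_len(nf)) {
    Af <- I2 + 0i
    for (k in seq_along(A))
      Af <- Af - A[[k]] * exp(-2i * pi * freqs[m] * k / fs)
    Hm <- solve(Af)
    H[, , m] <- Hm
    S[, , m] <- Hm %*% Sigma %*% Conj(t(Hm))
  }
  gc <- geweke_gc(S, H, Sigma)
  list(gc_xy = gc$gc_xy, gc_yx = gc$gc_yx, S = S, H = H, freqs = freqs)
}
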