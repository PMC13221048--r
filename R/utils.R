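## Internal numerical helpers shared across modules.

## Smallest power of two >= n (FFT-friendly lengths).
next_pow2 <- function(n) 2L^ceiling(log2(max(n, 1L)))

## Linear convolution of x with kernel h via FFT, returning the "same"
## segment aligned with x (kernel assumed centered at index `center`).
fft_convolve_same <- function(x, h, center = (length(h) + 1L) %/% 2L) {
  nx <- length(x); nh <- length(h)
  nfft <- next_pow2(nx + nh - 1L)
  y <- stats::fft(stats::fft(c(x, rep(0, nfft - nx))) *
                  stats::fft(c(h, rep(0, nfft - nh))), inverse = TRUE) / nfft
  y[center:(center + nx - 1L)]
}

## Analytic signal via frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Gaussian 1/f^alpha background noise, built in the frequency domain so the
## spectral slope is exact in expectation. Returns a real vector of length n.
one_over_f_noise <- function(n, fs, alpha = 1, amplitude = 1) {
  nfft <- if (n %% 2 == 0) n else n + 1L
  nf <- nfft / 2 - 1L
  f <- seq_len(nf) * fs / nfft
  mag <- f^(-alpha / 2)
  pos <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * mag
  nyq <- complex(real = stats::rnorm(1) * (fs / 2)^(-alpha / 2), imaginary = 0)
  spec <- c(0, pos, nyq, Conj(rev(pos)))
  x <- Re(stats::fft(spec, inverse = TRUE)) / sqrt(nfft)
  x <- x[seq_len(n)]
  x / stats::sd(x) * amplitude
}

## Zero-phase FIR band-pass. Order scales with the low cutoff so the filter
## spans ~3 cycles of the slowest component; bounded by the signal length.
bandpass_fir <- function(x, fs, band, order = NULL) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] < fs / 2, band[1] < band[2])
  if (is.null(order)) order <- round(3 * fs / band[1])
  order <- min(order, floor((length(x) - 1) / 3) - 1)
  order <- max(order + order %% 2, 4)  # even order -> symmetric FIR
  h <- as.numeric(signal::fir1(order, band / (fs / 2), type = "pass"))
  as.numeric(signal::filtfilt(h, 1, x))
}

## Label 8-connected components of a logical matrix. Returns an integer
## matrix (0 = background). Iterative flood fill; maps here are small.
label_components_8 <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cell - 1L) %% nr + 1L
      cl <- (cell - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cl + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        cell2 <- (c2 - 1L) * nr + r2
        if (mask[cell2] && lab[cell2] == 0L) {
          lab[cell2] <- cur
          stack <- c(stack, cell2)
        }
      }
    }
  }
  lab
}

## Deterministic child seed derived from a master seed and a stage tag,
## kept below 2^31.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.integer(seed) * 1013L + as.integer(h %% 99991L)) %% 2147483647L
}
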