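# Correlation classification, lagged cross-correlation, and multitaper
# coherence between neural activity and pupil size.
#
# DPSS (Slepian) tapers are computed from the classic symmetric tridiagonal
# form of the concentration problem: the top-k eigenvalues are located by
# Sturm-sequence bisection and the eigenvectors recovered by inverse
# iteration, which is O(n) per taper and exact to machine precision. The
# concentration ratios are then evaluated as the quadratic form of each taper
# with the sinc (Dirichlet) kernel.

# number of eigenvalues of the tridiagonal (d, e) strictly below each x
sturm_counts <- function(d, e2, xs) {
  q <- d[1] - xs
  cnt <- as.integer(q < 0)
  for (i in 2:length(d)) {
    q[q == 0] <- -1e-300
    q <- d[i] - xs - e2[i - 1] / q
    cnt <- cnt + (q < 0)
  }
  cnt
}

tridiag_top_eigenvalues <- function(d, e, k) {
  e2 <- e^2
  n <- length(d)
  r <- c(abs(e), 0) + c(0, abs(e))
  lo <- rep(min(d - r), k)
  hi <- rep(max(d + r), k)
  target <- n - seq_len(k)
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    cnt <- sturm_counts(d, e2, mid)
    up <- cnt > target
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
    if (max(hi - lo) <= 1e-12 * max(abs(hi), 1)) break
  }
  (lo + hi) / 2
}

# tridiagonal solve (A x = b) with partial pivoting; sub/sup are the off
# diagonals of the symmetric matrix minus the shift already applied to diag_
solve_tridiag_pp <- function(sub, diag_, sup, b) {
  n <- length(diag_)
  a <- c(sub, 0)       # a[i]: row i+1, col i
  dd <- diag_
  cc <- c(sup, 0)      # cc[i]: row i, col i+1
  ee <- numeric(n)     # fill-in: row i, col i+2
  x <- b
  for (i in seq_len(n - 1)) {
    if (abs(a[i]) > abs(dd[i])) {
      # swap rows i and i+1
      tmp <- dd[i]; dd[i] <- a[i]; a[i] <- tmp
      tmp <- cc[i]; cc[i] <- dd[i + 1]; dd[i + 1] <- tmp
      tmp <- ee[i]; ee[i] <- cc[i + 1]; cc[i + 1] <- tmp
      tmp <- x[i]; x[i] <- x[i + 1]; x[i + 1] <- tmp
    }
    if (dd[i] == 0) dd[i] <- 1e-300
    m <- a[i] / dd[i]
    dd[i + 1] <- dd[i + 1] - m * cc[i]
    cc[i + 1] <- cc[i + 1] - m * ee[i]
    x[i + 1] <- x[i + 1] - m * x[i]
  }
  if (dd[n] == 0) dd[n] <- 1e-300
  x[n] <- x[n] / dd[n]
  if (n >= 2) x[n - 1] <- (x[n - 1] - cc[n - 1] * x[n]) / dd[n - 1]
  if (n >= 3) {
    for (i in (n - 2):1) {
      x[i] <- (x[i] - cc[i] * x[i + 1] - ee[i] * x[i + 2]) / dd[i]
    }
  }
  x
}

tridiag_eigenvector <- function(d, e, lambda, prev = NULL) {
  n <- length(d)
  v <- sin(seq_len(n) * 0.7 + lambda %% 1)  # deterministic, non-degenerate init
  v <- v / sqrt(sum(v^2))
  for (iter in 1:4) {
    v <- solve_tridiag_pp(e, d - lambda, e, v)
    if (!is.null(prev)) {
      for (j in seq_len(ncol(prev))) v <- v - sum(v * prev[, j]) * prev[, j]
    }
    v <- v / sqrt(sum(v^2))
  }
  v
}

dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, unit energy, together with their concentration ratios
#' (eigenvalues of the sinc kernel). The sign convention makes each taper's
#' largest-magnitude sample positive.
#'
#' @param n Taper length (samples).
#' @param nw Time-bandwidth product (default 4, which yields at least 7
#'   well-concentrated tapers).
#' @param k Number of tapers (default 7).
#' @return List with `tapers` (n x k matrix, columns orthonormal) and
#'   `eigenvalues` (concentrations in (0, 1)).
#' @export
dpss_tapers <- function(n, nw = 4, k = 7) {
  if (k >= n || n < 8) {
    pc_stop("trace shorter than the taper support", "pc_trace_too_short")
  }
  stopifnot(nw > 0, nw < n / 2, k >= 1)
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(dpss_cache[[key]])) return(dpss_cache[[key]])

  W <- nw / n
  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  evals <- tridiag_top_eigenvalues(d, e, k)
  V <- matrix(0, n, k)
  for (j in seq_len(k)) {
    prev <- if (j > 1) V[, seq_len(j - 1), drop = FALSE] else NULL
    v <- tridiag_eigenvector(d, e, evals[j], prev)
    if (v[which.max(abs(v))] < 0) v <- -v
    V[, j] <- v
  }

  # concentrations: quadratic form with the sinc kernel, via FFT convolution
  m <- 1:(n - 1)
  cvec <- c(2 * W, sin(2 * pi * W * m) / (pi * m))
  kern <- c(rev(cvec[-1]), cvec)
  lambda <- vapply(seq_len(k), function(j) {
    full <- stats::convolve(V[, j], rev(kern), type = "open")
    sum(V[, j] * full[n:(2 * n - 1)])
  }, numeric(1))
  lambda <- pmin(pmax(lambda, 1e-12), 1 - 1e-14)

  out <- list(tapers = V, eigenvalues = lambda)
  dpss_cache[[key]] <- out
  out
}

# Thomson adaptive weights for one signal: eigenspectra S_k (nf x k),
# concentrations lambda, process variance sig2. Returns the weight matrix
# d_k(f) = sqrt(lambda_k) * b_k(f).
adaptive_weights <- function(S_k, lambda, sig2) {
  nf <- nrow(S_k)
  k <- ncol(S_k)
  lam <- rep(lambda, each = nf)
  S <- if (k >= 2) (S_k[, 1] + S_k[, 2]) / 2 else S_k[, 1]
  b <- NULL
  for (iter in 1:100) {
    b <- S / (lam * S + (1 - lam) * sig2)
    dim(b) <- c(nf, k)
    wk <- b^2 * lam
    dim(wk) <- c(nf, k)
    S_new <- rowSums(wk * S_k) / rowSums(wk)
    if (max(abs(S_new - S)) <= 1e-10 * max(S_new)) {
      S <- S_new
      break
    }
    S <- S_new
  }
  b <- S / (lam * S + (1 - lam) * sig2)
  dim(b) <- c(nf, k)
  b * rep(sqrt(lambda), each = nf)
}

#' Multitaper coherence between two traces
#'
#' Magnitude-squared coherence estimated with DPSS tapers over a single epoch
#' spanning the entire trace. With `adaptive = TRUE` (default) each signal's
#' eigenspectra are combined with Thomson adaptive weights from the first
#' `n_tapers` tapers; otherwise tapers are weighted uniformly. Coherence is
#' bounded in [0, 1] by the Cauchy--Schwarz inequality and is symmetric in
#' its arguments and invariant to rescaling either input.
#'
#' @param x,y Equal-length traces on a common clock.
#' @param rate_hz Sampling rate in Hz.
#' @param n_tapers Number of tapers (default 7).
#' @param nw Time-bandwidth product (default 4).
#' @param adaptive Use adaptive eigenvalue weighting (default TRUE).
#' @return Object of class `coherence_spectrum`: list with `frequency_hz`
#'   (up to Nyquist), `coherence`, `n_tapers`, `nw`, and the resolution
#'   `bandwidth_hz = nw * rate_hz / n`.
#' @export
multitaper_coherence <- function(x, y, rate_hz, n_tapers = 7, nw = 4,
                                 adaptive = TRUE) {
  if (length(x) != length(y)) {
    pc_stop("traces must have equal length", "pc_invalid_input")
  }
  n <- length(x)
  dp <- dpss_tapers(n, nw = nw, k = n_tapers)
  x <- x - mean(x)
  y <- y - mean(y)
  nf <- floor(n / 2) + 1
  Xf <- stats::mvfft(dp$tapers * x)[seq_len(nf), , drop = FALSE]
  Yf <- stats::mvfft(dp$tapers * y)[seq_len(nf), , drop = FALSE]
  Sx_k <- Mod(Xf)^2
  Sy_k <- Mod(Yf)^2
  if (adaptive && n_tapers >= 2) {
    dx <- adaptive_weights(Sx_k, dp$eigenvalues, mean(x^2))
    dy <- adaptive_weights(Sy_k, dp$eigenvalues, mean(y^2))
  } else {
    dx <- dy <- matrix(1, nf, n_tapers)
  }
  sxx <- rowSums(dx^2 * Sx_k)
  syy <- rowSums(dy^2 * Sy_k)
  sxy <- rowSums(dx * dy * Xf * Conj(Yf))
  coh <- Mod(sxy)^2 / (sxx * syy)
  structure(list(frequency_hz = (seq_len(nf) - 1) * rate_hz / n,
                 coherence = as.numeric(coh),
                 n_tapers = n_tapers, nw = nw,
                 bandwidth_hz = nw * rate_hz / n),
            class = "coherence_spectrum")
}

#' Group-averaged multitaper coherence
#'
#' Clips every subject's trace pair to the shortest length across subjects,
#' computes the per-subject coherence spectrum over the full (clipped) epoch,
#' and averages the spectra pointwise.
#'
#' @param xs,ys Lists of per-subject traces (paired by position).
#' @param rate_hz Common sampling rate.
#' @param ... Passed to [multitaper_coherence()].
#' @return Object of class `coherence_spectrum` with the group `coherence`
#'   mean and a `subjects` matrix (subject x frequency).
#' @export
multitaper_coherence_group <- function(xs, ys, rate_hz, ...) {
  stopifnot(length(xs) == length(ys), length(xs) >= 1)
  n_min <- min(c(vapply(xs, length, integer(1)),
                 vapply(ys, length, integer(1))))
  spectra <- lapply(seq_along(xs), function(i) {
    multitaper_coherence(xs[[i]][seq_len(n_min)], ys[[i]][seq_len(n_min)],
                         rate_hz, ...)
  })
  mat <- do.call(rbind, lapply(spectra, `[[`, "coherence"))
  out <- spectra[[1]]
  out$coherence <- colMeans(mat)
  out$subjects <- mat
  out
}

#' Normalised lagged cross-correlation
#'
#' Biased cross-correlation (covariances divided by n, normalised by the two
#' standard deviations; stable at large lags). Sign convention: a peak at a
#' positive lag means the first argument leads the second.
#'
#' @param x,y Equal-length traces.
#' @param max_lag_s Maximum lag magnitude in seconds.
#' @param rate_hz Sampling rate in Hz.
#' @return List with `lag_s`, `cc`, `peak_lag_s`, `peak_value` (signed value
#'   at the largest |cc|), and the stated `convention`.
#' @export
cross_correlation <- function(x, y, max_lag_s, rate_hz) {
  if (length(x) != length(y)) {
    pc_stop("traces must have equal length", "pc_invalid_input")
  }
  L <- round(max_lag_s * rate_hz)
  if (L >= length(x)) {
    pc_stop("max_lag must be shorter than the trace", "pc_invalid_input")
  }
  # ccf(y, x)[k] = cor(y[t+k], x[t]); positive k then means x leads y
  cc <- stats::ccf(y, x, lag.max = L, plot = FALSE, demean = TRUE)
  lags <- as.numeric(cc$lag) / rate_hz
  v <- as.numeric(cc$acf)
  peak <- which.max(abs(v))
  list(lag_s = lags, cc = v, peak_lag_s = lags[peak], peak_value = v[peak],
       convention = "positive peak lag: first argument leads the second")
}

#' Correlation-based pupil ON/OFF classification
#'
#' Pearson correlation of each cell with the pupil trace; cells with r > 0
#' are pupil-ON, cells with r < 0 pupil-OFF. Intended for cells that survive
#' the encoding-model r^2 filter.
#'
#' @param cells Matrix of cell traces (time x cell), aligned with `pupil`.
#' @param pupil Pupil trace on the same clock.
#' @return data.frame with `cell_id`, `r`, `label` ("ON"/"OFF").
#' @export
correlate_and_classify <- function(cells, pupil) {
  cells <- as.matrix(cells)
  if (stats::sd(pupil) == 0 || any(apply(cells, 2, stats::sd) == 0)) {
    pc_stop("zero-variance input to correlation", "pc_zero_variance")
  }
  r <- as.numeric(stats::cor(pupil, cells))
  data.frame(cell_id = seq_len(ncol(cells)), r = r,
             label = ifelse(r > 0, "ON", ifelse(r < 0, "OFF", NA)))
}
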