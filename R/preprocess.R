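# Trace preprocessing: neuropil-corrected dF/F, duplicate-ROI merging,
# smoothing + z-scoring for imaging; convex-hull detrending for photometry.
# Pipeline order is fixed: correct -> merge -> smooth -> z-score (imaging);
# detrend -> z-score (photometry).

#' Neuropil-corrected dF/F
#'
#' Subtracts the halo (neuropil) trace from the cell ROI trace (plain
#' subtraction, no scaling coefficient), then forms
#' `dF/F = (F - F0) / |F0|` with `F0` the `baseline_percentile`-th percentile
#' of the corrected trace. A baseline whose magnitude falls below
#' `1e-6 * sd(cell_raw)` is flagged as pathological and raises an error.
#'
#' @param cell_raw Raw ROI mean-intensity trace.
#' @param halo_raw Halo (neuropil) mean-intensity trace, same length.
#' @param baseline_percentile Percentile (0--100) defining F0; default 10.
#' @return dF/F trace (unitless).
#' @export
neuropil_correct_dff <- function(cell_raw, halo_raw, baseline_percentile = 10) {
  if (length(cell_raw) != length(halo_raw) ||
      !all(is.finite(cell_raw)) || !all(is.finite(halo_raw))) {
    pc_stop("cell and halo traces must be finite and equal length",
            "pc_invalid_input")
  }
  f <- cell_raw - halo_raw
  f0 <- unname(stats::quantile(f, baseline_percentile / 100))
  scale <- stats::sd(cell_raw)
  if (!is.finite(scale) || scale == 0) scale <- 1
  if (abs(f0) < 1e-6 * scale) {
    pc_stop(sprintf("pathological dF/F baseline: |F0| = %.3g", abs(f0)),
            "pc_degenerate_baseline")
  }
  (f - f0) / abs(f0)
}

#' Merge duplicate-plane ROIs
#'
#' Cells imaged in multiple Z-planes appear as several ROIs; each duplicate
#' group is replaced by the unweighted mean of its member traces. Ungrouped
#' ROIs pass through unchanged, in their original column positions (a group
#' sits at its first member's position).
#'
#' @param traces Numeric matrix, one column per ROI.
#' @param duplicate_groups List of integer (or column-name) vectors; groups
#'   must not overlap.
#' @return Matrix with one column per output cell.
#' @export
merge_duplicate_cells <- function(traces, duplicate_groups = list()) {
  traces <- as.matrix(traces)
  if (length(duplicate_groups) == 0) return(traces)
  idx <- lapply(duplicate_groups, function(g) {
    if (is.character(g)) match(g, colnames(traces)) else as.integer(g)
  })
  flat <- unlist(idx)
  if (anyNA(flat) || any(flat < 1) || any(flat > ncol(traces))) {
    pc_stop("duplicate group references an unknown ROI", "pc_invalid_input")
  }
  if (anyDuplicated(flat)) {
    pc_stop("duplicate groups overlap", "pc_overlapping_groups")
  }
  keep <- setdiff(seq_len(ncol(traces)), flat)
  first <- vapply(idx, min, integer(1))
  merged <- vapply(idx, function(g) rowMeans(traces[, g, drop = FALSE]),
                   numeric(nrow(traces)))
  out <- cbind(traces[, keep, drop = FALSE], merged)
  out[, order(c(keep, first)), drop = FALSE]
}

#' Three-sample moving average followed by z-scoring
#'
#' Centred 3-tap moving average; at the edges the window shrinks to the
#' available samples (no phantom zeros), preserving trace length. The
#' smoothed trace is then z-scored over its full length, so the output always
#' has mean 0 and sd 1.
#'
#' @param x Numeric trace, length >= 3.
#' @return Smoothed, z-scored trace.
#' @export
smooth_and_zscore <- function(x) {
  n <- length(x)
  if (n < 3) pc_stop("trace must have length >= 3", "pc_invalid_input")
  sm <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  sm[1] <- mean(x[1:2])
  sm[n] <- mean(x[(n - 1):n])
  zscore(sm)
}

#' Convex-hull detrending for photometry traces
#'
#' Computes the lower convex hull of `(index, value)`, scans its vertices
#' forward in time keeping only those with strictly decreasing values (the
#' first vertex is always kept), linearly interpolates this template to the
#' full trace length -- holding the last kept value to the end -- subtracts
#' it, and z-scores the residual. The template is non-increasing by
#' construction. A residual with zero variance signals a pure-trend trace and
#' raises an error.
#'
#' @param x Raw photometry trace, length >= 2, finite.
#' @return List with `detrended` (z-scored residual) and `template`.
#' @export
convex_hull_detrend <- function(x) {
  n <- length(x)
  if (n < 2 || !all(is.finite(x))) {
    pc_stop("trace must be finite with length >= 2", "pc_invalid_input")
  }
  hull <- lower_hull_indices(x)
  keep <- hull[1]
  last <- x[hull[1]]
  for (i in hull[-1]) {
    if (x[i] < last) {
      keep <- c(keep, i)
      last <- x[i]
    }
  }
  template <- if (length(keep) == 1) {
    rep(x[keep], n)
  } else {
    stats::approx(keep, x[keep], xout = seq_len(n), rule = 2)$y
  }
  residual <- x - template
  if (stats::sd(residual) == 0) {
    pc_stop("residual has zero variance: trace is pure trend",
            "pc_zero_variance")
  }
  list(detrended = zscore(residual), template = template)
}

# Lower convex hull of (1:n, x) by Andrew's monotone chain; returns indices
# in increasing order. Endpoints are always included.
lower_hull_indices <- function(x) {
  n <- length(x)
  if (n <= 2) return(seq_len(n))
  h <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      # cross product of (h[k-1] -> h[k]) x (h[k-1] -> i); keep right turns
      o <- (h[k] - h[k - 1L]) * (x[i] - x[h[k - 1L]]) -
        (x[h[k]] - x[h[k - 1L]]) * (i - h[k - 1L])
      if (o <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    h[k] <- i
  }
  h[seq_len(k)]
}

#' Imaging preprocessing pipeline
#'
#' Fixed-order pipeline for cell traces: neuropil correction, duplicate-ROI
#' merging, 3-sample smoothing and z-scoring.
#'
#' @param raw Matrix of raw ROI traces (time x ROI).
#' @param halo Matrix of halo traces, same shape.
#' @param duplicate_groups Passed to [merge_duplicate_cells()].
#' @param baseline_percentile Passed to [neuropil_correct_dff()].
#' @return Matrix of processed (z-scored) dF/F traces, with attribute
#'   `pipeline` recording the applied order.
#' @export
preprocess_cells <- function(raw, halo, duplicate_groups = list(),
                             baseline_percentile = 10) {
  raw <- as.matrix(raw)
  halo <- as.matrix(halo)
  stopifnot(identical(dim(raw), dim(halo)))
  dff <- vapply(seq_len(ncol(raw)),
                function(j) neuropil_correct_dff(raw[, j], halo[, j],
                                                 baseline_percentile),
                numeric(nrow(raw)))
  merged <- merge_duplicate_cells(dff, duplicate_groups)
  out <- apply(merged, 2, smooth_and_zscore)
  attr(out, "pipeline") <- c("neuropil_correct", "merge_duplicates",
                             "smooth_3pt", "zscore")
  out
}
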