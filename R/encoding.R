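# Per-cell encoding model: OLS regression of cell activity on z-scored
# pupil, locomotion and reward predictors, the r^2 >= 0.05 filter,
# leave-one-predictor-out variance partitioning, and cell classification.

#' Raised-cosine reward spline basis
#'
#' A finite candidate set of causal kernels for convolving the lick square
#' wave into a reward-consumption regressor. Each kernel is a single raised
#' cosine bump `0.5 * (1 - cos(2*pi*t/S))` on `[0, S]`, non-negative,
#' finitely supported and unit-area normalised. Supports are log-spaced over
#' `support_range_s`.
#'
#' @param rate_hz Sampling rate of the trace the kernels will be applied to.
#' @param n_kernels Number of candidate kernels (default 8).
#' @param support_range_s Length-2 range of kernel supports in seconds
#'   (default 0.5--8 s).
#' @return Object of class `spline_basis`: list with `kernels` (each having
#'   `support_s` and `values`) and `rate_hz`.
#' @export
make_spline_basis <- function(rate_hz, n_kernels = 8,
                              support_range_s = c(0.5, 8)) {
  stopifnot(rate_hz > 0, n_kernels >= 1, support_range_s[1] > 0)
  supports <- exp(seq(log(support_range_s[1]), log(support_range_s[2]),
                      length.out = n_kernels))
  kernels <- lapply(supports, function(S) {
    t <- seq(0, S, by = 1 / rate_hz)
    v <- 0.5 * (1 - cos(2 * pi * t / S))
    list(support_s = S, values = v / (sum(v) / rate_hz))
  })
  structure(list(kernels = kernels, rate_hz = rate_hz),
            class = "spline_basis")
}

#' Build pupil and locomotion predictors on the cell clock
#'
#' Linearly interpolates the pupil radius and running speed onto the imaging
#' clock and z-scores them. A zero-variance trace (e.g. a session without
#' running) is excluded with a warning.
#'
#' @param pupil_trace `pupil_trace` data.frame (or list with `time_s`,
#'   `radius_px`).
#' @param speed_time_s,speed_cmps Running-speed trace.
#' @param cell_time_s Imaging clock sample times.
#' @return Numeric matrix with columns among `pupil`, `locomotion`.
#' @export
build_predictors <- function(pupil_trace, speed_time_s, speed_cmps,
                             cell_time_s) {
  cols <- list(
    pupil = resample_linear(pupil_trace$time_s, pupil_trace$radius_px,
                            cell_time_s),
    locomotion = resample_linear(speed_time_s, speed_cmps, cell_time_s)
  )
  out <- list()
  for (nm in names(cols)) {
    if (stats::sd(cols[[nm]]) == 0) {
      warning(sprintf("predictor '%s' has zero variance and is excluded", nm))
    } else {
      out[[nm]] <- zscore(cols[[nm]])
    }
  }
  do.call(cbind, out)
}

# r^2 of every column of Y against design X (with intercept), via one QR.
r2_matrix <- function(Y, X) {
  Q <- qr.Q(qr(cbind(1, X)))
  Yc <- sweep(Y, 2, colMeans(Y))
  tss <- colSums(Yc^2)
  proj <- Q %*% (t(Q) %*% Y)
  rss <- colSums((Y - proj)^2)
  pmin(pmax(1 - rss / tss, 0), 1)
}

#' Choose the reward spline and build the reward regressor
#'
#' Convolves the lick square wave with every kernel of the basis, runs the
#' full three-predictor regression for every cell under each candidate, and
#' picks the kernel that yields the highest full-model r^2 for the largest
#' number of cells (per-cell argmax vote; ties go to the earlier kernel).
#' The alternative selection rule -- maximising the mean r^2 across cells --
#' is available via `method = "mean_r2"`.
#'
#' @param lick Lick square wave on the cell clock.
#' @param basis A [make_spline_basis()] object.
#' @param cells Matrix of processed cell traces (time x cell).
#' @param base_predictors Matrix with the remaining predictors (pupil,
#'   locomotion) on the cell clock.
#' @param method `"vote"` (default) or `"mean_r2"`.
#' @return List with `kernel_index`, `kernel`, z-scored `regressor`, the
#'   per-kernel `votes`, the cell x kernel `r2` matrix, and `excluded`
#'   (TRUE when the lick wave has zero variance, with a warning).
#' @export
build_reward_regressor <- function(lick, basis, cells, base_predictors,
                                   method = c("vote", "mean_r2")) {
  method <- match.arg(method)
  if (length(basis$kernels) == 0) {
    pc_stop("spline basis is empty", "pc_invalid_input")
  }
  cells <- as.matrix(cells)
  if (stats::sd(lick) == 0) {
    warning("lick wave has zero variance; reward regressor excluded from the model")
    return(list(kernel_index = NA_integer_, kernel = NULL, regressor = NULL,
                votes = NULL, r2 = NULL, excluded = TRUE))
  }
  K <- length(basis$kernels)
  regs <- vapply(basis$kernels,
                 function(k) zscore(conv_causal(lick, k$values)),
                 numeric(length(lick)))
  r2 <- vapply(seq_len(K), function(k) {
    r2_matrix(cells, cbind(base_predictors, reward = regs[, k]))
  }, numeric(ncol(cells)))
  r2 <- matrix(r2, ncol = K)
  if (method == "vote") {
    votes_per_cell <- apply(r2, 1, which.max)   # earliest kernel wins ties
    votes <- tabulate(votes_per_cell, nbins = K)
    choice <- which.max(votes)
  } else {
    votes <- colMeans(r2)
    choice <- which.max(votes)
  }
  list(kernel_index = choice, kernel = basis$kernels[[choice]],
       regressor = regs[, choice], votes = votes, r2 = r2, excluded = FALSE)
}

#' Fit the full encoding model for one cell
#'
#' Ordinary least squares with intercept; `r^2 = 1 - SS_res / SS_tot`. The
#' model is fit in-sample, matching how the per-cell explained variance is
#' reported downstream.
#'
#' @param cell Cell activity trace (dependent variable).
#' @param predictors Numeric matrix of predictors (columns named).
#' @return List with `coefficients` (named, excluding intercept),
#'   `intercept`, and `r2`.
#' @export
fit_full_model <- function(cell, predictors) {
  X <- as.matrix(predictors)
  if (length(cell) != nrow(X) || !all(is.finite(cell)) || !all(is.finite(X))) {
    pc_stop("cell and predictors must be finite and equal length",
            "pc_invalid_input")
  }
  if (length(cell) < 10 * ncol(X)) {
    pc_stop("need at least 10x more samples than predictors",
            "pc_invalid_input")
  }
  D <- cbind(`(Intercept)` = 1, X)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    dropped <- colnames(D)[qd$pivot[(qd$rank + 1):ncol(D)]]
    pc_stop(sprintf("rank-deficient design; collinear predictor(s): %s",
                    paste(dropped, collapse = ", ")),
            "pc_rank_deficient")
  }
  coef <- qr.coef(qd, cell)
  fitted <- D %*% coef
  rss <- sum((cell - fitted)^2)
  tss <- sum((cell - mean(cell))^2)
  list(coefficients = coef[-1], intercept = unname(coef[1]),
       r2 = unname(1 - rss / tss))
}

#' Filter cells by explained variance
#'
#' Keeps cells whose full-model r^2 is at least `threshold` (strict reading:
#' cells with r^2 below the threshold are removed, so the boundary value is
#' kept).
#'
#' @param results data.frame with an `r2_full` column (as from
#'   [encode_cells()]).
#' @param threshold Minimum full-model r^2 (default 0.05).
#' @return The kept subset of `results`.
#' @export
filter_cells <- function(results, threshold = 0.05) {
  kept <- results[results$r2_full >= threshold, , drop = FALSE]
  if (nrow(kept) == 0) warning("no cell passes the r2 filter")
  message(sprintf("filter_cells: kept %d of %d cells (r2 >= %.2g)",
                  nrow(kept), nrow(results), threshold))
  kept
}

#' Leave-one-predictor-out variance contributions
#'
#' Refits the model with each predictor removed and expresses the drop in
#' explained variance as a percentage of the full model's r^2:
#' `contribution(v) = 100 * (1 - r2_without_v / r2_full)`. With correlated
#' predictors the raw value can be negative (shared variance); raw values are
#' returned alongside a zero-floored version.
#'
#' @param cell Cell activity trace.
#' @param predictors Full predictor matrix (named columns).
#' @param r2_full Optional precomputed full-model r^2.
#' @return data.frame with one row per predictor: `predictor`, `r2_reduced`,
#'   `contribution` (floored at 0) and `contribution_raw`.
#' @export
variance_contributions <- function(cell, predictors, r2_full = NULL) {
  X <- as.matrix(predictors)
  if (is.null(r2_full)) r2_full <- fit_full_model(cell, X)$r2
  if (r2_full <= 0) {
    pc_stop("full-model r2 is zero; contributions are undefined",
            "pc_invalid_input")
  }
  res <- lapply(seq_len(ncol(X)), function(j) {
    r2_red <- fit_full_model(cell, X[, -j, drop = FALSE])$r2
    raw <- 100 * (1 - r2_red / r2_full)
    data.frame(predictor = colnames(X)[j], r2_reduced = r2_red,
               contribution = max(raw, 0), contribution_raw = raw)
  })
  do.call(rbind, res)
}

#' Classify cells from their contributions
#'
#' A cell is labelled `"pupil"` when its pupil contribution reaches
#' `major_cutoff` percent and its reward contribution does not, `"reward"`
#' symmetrically, `"both"` when both reach the cutoff, and `"other"`
#' otherwise.
#'
#' @param contributions data.frame with `contrib_pupil` and `contrib_reward`
#'   columns (percent).
#' @param major_cutoff Percent cutoff (default 20).
#' @return Character vector of labels.
#' @export
classify_cells <- function(contributions, major_cutoff = 20) {
  p <- contributions$contrib_pupil >= major_cutoff
  r <- contributions$contrib_reward >= major_cutoff
  ifelse(p & r, "both", ifelse(p, "pupil", ifelse(r, "reward", "other")))
}

#' Per-variable contribution histograms above a minor cutoff
#'
#' @param results data.frame from [encode_cells()] (kept cells).
#' @param minor_cutoff Percent; only contributions above it are returned
#'   (default 10).
#' @return Named list of contribution vectors, one per predictor.
#' @export
contribution_histograms <- function(results, minor_cutoff = 10) {
  cols <- grep("^contrib_", names(results), value = TRUE)
  out <- lapply(cols, function(cn) {
    v <- results[[cn]]
    v[v > minor_cutoff]
  })
  names(out) <- sub("^contrib_", "", cols)
  out
}

#' Run the full encoding model over a cell population
#'
#' Fits the full OLS model per cell, applies the r^2 filter, computes
#' leave-one-out contributions for the kept cells and classifies them.
#' Nested-model monotonicity (`r2_reduced <= r2_full`) is asserted on every
#' cell.
#'
#' @param cells Matrix of processed traces (time x cell).
#' @param predictors Predictor matrix (named columns, z-scored).
#' @param r2_threshold Keep cells with `r2_full >= r2_threshold`.
#' @param major_cutoff Classification cutoff in percent.
#' @return data.frame (one row per cell): `cell_id`, `b_<predictor>`
#'   coefficients, `r2_full`, `r2_minus_<predictor>`,
#'   `contrib_<predictor>` (floored) and `contrib_<predictor>_raw`, `kept`,
#'   `label` (NA for removed cells).
#' @export
encode_cells <- function(cells, predictors, r2_threshold = 0.05,
                         major_cutoff = 20) {
  cells <- as.matrix(cells)
  X <- as.matrix(predictors)
  pn <- colnames(X)
  n_cells <- ncol(cells)
  fits <- lapply(seq_len(n_cells), function(i) fit_full_model(cells[, i], X))
  r2_full <- vapply(fits, `[[`, numeric(1), "r2")
  coefs <- t(vapply(fits, `[[`, numeric(ncol(X)), "coefficients"))
  r2_red <- vapply(seq_len(ncol(X)), function(j) {
    r2_matrix(cells, X[, -j, drop = FALSE])
  }, numeric(n_cells))
  r2_red <- matrix(r2_red, ncol = ncol(X))
  stopifnot(all(r2_red <= r2_full + 1e-12))  # nested-model monotonicity
  raw <- 100 * (1 - r2_red / r2_full)
  contrib <- pmax(raw, 0)

  out <- data.frame(cell_id = seq_len(n_cells))
  for (j in seq_along(pn)) out[[paste0("b_", pn[j])]] <- coefs[, j]
  out$r2_full <- r2_full
  for (j in seq_along(pn)) out[[paste0("r2_minus_", pn[j])]] <- r2_red[, j]
  for (j in seq_along(pn)) out[[paste0("contrib_", pn[j])]] <- contrib[, j]
  for (j in seq_along(pn)) out[[paste0("contrib_", pn[j], "_raw")]] <- raw[, j]
  out$kept <- r2_full >= r2_threshold
  out$label <- NA_character_
  if (all(c("pupil", "reward") %in% pn) && any(out$kept)) {
    out$label[out$kept] <- classify_cells(out[out$kept, ], major_cutoff)
  }
  out
}
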