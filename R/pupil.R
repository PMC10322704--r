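# Pupil extraction: landmark frames -> radius/area time series, plus
# event-aligned pupil responses.

#' Algebraic (Kasa) circle fit
#'
#' Fits a circle to 2-D points by the Kasa algebraic least-squares method:
#' minimise `sum((x^2 + y^2 + D*x + E*y + F)^2)` over `(D, E, F)`, a linear
#' problem with a closed-form solution. Deterministic, order-invariant,
#' translation-equivariant and rotation-invariant in the radius.
#'
#' @param points Numeric matrix with >= 3 rows and columns (x, y), in pixels.
#'   Image convention: x right, y down, origin top-left; the radius does not
#'   depend on the convention.
#' @return List with `center` (length-2) and `radius` (> 0).
#' @seealso [extract_pupil_trace()]
#' @export
fit_circle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3 || ncol(points) != 2 || !all(is.finite(points))) {
    pc_stop("need >= 3 finite (x, y) points", "pc_degenerate_geometry")
  }
  A <- cbind(points, 1)
  b <- -(points[, 1]^2 + points[, 2]^2)
  qa <- qr(A)
  if (qa$rank < 3) {
    pc_stop("points are collinear; circle fit is degenerate",
            "pc_degenerate_geometry")
  }
  coef <- qr.coef(qa, b)
  center <- -coef[1:2] / 2
  r2 <- sum(center^2) - coef[3]
  if (!is.finite(r2) || r2 <= 0) {
    pc_stop("degenerate circle fit (non-positive radius)",
            "pc_degenerate_geometry")
  }
  list(center = unname(center), radius = sqrt(r2))
}

#' Extract a pupil trace from landmark frames
#'
#' Per-point, frames whose likelihood falls below `confidence_threshold` are
#' replaced by linear interpolation of that point's coordinates between the
#' nearest flanking above-threshold frames (leading/trailing gaps take the
#' nearest valid value). A circle is then fitted per frame; frames where the
#' fit itself is degenerate get their radius interpolated from neighbouring
#' valid fits. The `interpolated` mask marks every frame where any point or
#' the fit was replaced.
#'
#' @param frames A `landmark_frames` object (from [render_landmarks()] or
#'   [read_landmarks_dlc()]).
#' @param confidence_threshold Likelihood below which a point is unusable.
#' @return data.frame of class `pupil_trace` with columns `time_s`,
#'   `radius_px`, `area_px2` (`= pi * radius^2`) and logical `interpolated`.
#' @export
extract_pupil_trace <- function(frames, confidence_threshold = 0.9) {
  n <- length(frames$time_s)
  if (is.unsorted(frames$time_s, strictly = TRUE)) {
    pc_stop("frames must be strictly time-ordered", "pc_invalid_input")
  }
  good <- frames$confidence >= confidence_threshold
  if (!any(rowSums(good) == 8)) {
    pc_stop("no frame has all points above the confidence threshold",
            "pc_no_valid_frames")
  }
  x <- frames$x
  y <- frames$y
  any_replaced <- rowSums(!good) > 0
  for (j in 1:8) {
    bad <- !good[, j]
    if (any(bad)) {
      ok <- which(!bad)
      if (length(ok) == 0) {
        pc_stop(sprintf("landmark point %d has no above-threshold frames", j),
                "pc_no_valid_frames")
      }
      x[bad, j] <- stats::approx(ok, x[ok, j], xout = which(bad), rule = 2)$y
      y[bad, j] <- stats::approx(ok, y[ok, j], xout = which(bad), rule = 2)$y
    }
  }

  radius <- rep(NA_real_, n)
  fit_failed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    fit <- tryCatch(fit_circle(cbind(x[i, ], y[i, ])),
                    pc_degenerate_geometry = function(e) NULL)
    if (is.null(fit)) fit_failed[i] <- TRUE else radius[i] <- fit$radius
  }
  if (all(fit_failed)) {
    pc_stop("circle fit failed on every frame", "pc_no_valid_frames")
  }
  if (any(fit_failed)) {
    ok <- which(!fit_failed)
    radius[fit_failed] <- stats::approx(ok, radius[ok],
                                        xout = which(fit_failed), rule = 2)$y
  }

  out <- data.frame(time_s = frames$time_s, radius_px = radius,
                    area_px2 = pi * radius^2,
                    interpolated = any_replaced | fit_failed)
  class(out) <- c("pupil_trace", "data.frame")
  out
}

#' Align a trace to events
#'
#' Cuts fixed peri-event windows out of a uniformly sampled trace. Events
#' whose window does not fit inside the trace are dropped (with a message).
#' Baseline and response are per-event means over the stated sub-windows;
#' the s.e.m. uses the number of retained events.
#'
#' @param time_s Sample times (uniform rate).
#' @param values Trace values.
#' @param event_times_s Event times in seconds.
#' @param window_s Length-2 peri-event window (pre, post) in seconds.
#' @param baseline_window_s Length-2 window (relative to the event) averaged
#'   into the per-event baseline.
#' @param response_window_s Length-2 window averaged into the per-event
#'   response.
#' @return Object of class `aligned_response`: list with `matrix` (event x
#'   time), `window_time_s`, `mean`, `sem`, per-event `baseline` and
#'   `response`, their means, and `n_events` / `n_dropped`.
#' @export
align_to_events <- function(time_s, values, event_times_s,
                            window_s = c(-2, 8),
                            baseline_window_s = c(-2, 0),
                            response_window_s = c(4, 8)) {
  stopifnot(length(time_s) == length(values), length(window_s) == 2)
  dt <- time_s[2] - time_s[1]
  n <- length(time_s)
  rel_idx <- seq(round(window_s[1] / dt), round(window_s[2] / dt))
  ev_idx <- round((event_times_s - time_s[1]) / dt) + 1
  fits <- ev_idx + rel_idx[1] >= 1 & ev_idx + rel_idx[length(rel_idx)] <= n
  if (!all(fits)) {
    message(sprintf("align_to_events: dropped %d of %d events without a full window",
                    sum(!fits), length(ev_idx)))
  }
  ev_idx <- ev_idx[fits]
  if (length(ev_idx) == 0) {
    pc_stop("no event has a full window inside the trace", "pc_no_events")
  }
  m <- t(vapply(ev_idx, function(i) values[i + rel_idx],
                numeric(length(rel_idx))))
  wt <- rel_idx * dt
  in_win <- function(w) wt >= w[1] & wt <= w[2]
  baseline <- rowMeans(m[, in_win(baseline_window_s), drop = FALSE])
  response <- rowMeans(m[, in_win(response_window_s), drop = FALSE])
  structure(list(
    matrix = m, window_time_s = wt,
    mean = colMeans(m),
    sem = apply(m, 2, stats::sd) / sqrt(nrow(m)),
    baseline = baseline, response = response,
    baseline_mean = mean(baseline), response_mean = mean(response),
    n_events = nrow(m), n_dropped = sum(!fits)
  ), class = "aligned_response")
}

#' Read a DeepLabCut-dialect landmark CSV
#'
#' Expects the 3-row DeepLabCut header (scorer / bodyparts / coords) with
#' x, y, likelihood triplets for 8 pupil-edge points, and a leading frame
#' index column. Frame times are reconstructed as `index / fps`.
#'
#' @param path CSV path.
#' @param fps Video frame rate in Hz.
#' @return A `landmark_frames` object.
#' @export
read_landmarks_dlc <- function(path, fps = 20) {
  if (!file.exists(path)) {
    pc_stop(sprintf("landmark file not found: %s", path), "pc_missing_file")
  }
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         colClasses = "character")
  coords <- as.character(hdr[3, -1])
  if (length(coords) %% 3 != 0 ||
      !all(coords == rep(c("x", "y", "likelihood"), length(coords) / 3))) {
    pc_stop("not a DeepLabCut landmark CSV: coords row must repeat x,y,likelihood",
            "pc_schema_error")
  }
  npts <- length(coords) / 3
  if (npts != 8) {
    pc_stop(sprintf("expected 8 landmark points, found %d", npts),
            "pc_schema_error")
  }
  d <- as.matrix(data.table::fread(path, skip = 3, header = FALSE))
  d <- d[, -1, drop = FALSE]
  n <- nrow(d)
  sel <- function(k) d[, seq(k, 24, by = 3), drop = FALSE]
  structure(list(time_s = (seq_len(n) - 1) / fps,
                 x = sel(1), y = sel(2), confidence = sel(3),
                 blink = rep(NA, n), rate_hz = fps),
            class = "landmark_frames")
}

#' Write landmarks as a DeepLabCut-dialect CSV
#'
#' @param frames A `landmark_frames` object.
#' @param path Output CSV path.
#' @param scorer Scorer name placed in the first header row.
#' @return `path`, invisibly.
#' @export
write_landmarks_dlc <- function(frames, path, scorer = "synthetic") {
  n <- length(frames$time_s)
  cols <- vector("list", 24)
  for (j in 1:8) {
    cols[[3 * j - 2]] <- frames$x[, j]
    cols[[3 * j - 1]] <- frames$y[, j]
    cols[[3 * j]] <- frames$confidence[, j]
  }
  body <- vapply(cols, function(v) sprintf("%.17g", v), character(n))
  lines <- c(
    paste(c("scorer", rep(scorer, 24)), collapse = ","),
    paste(c("bodyparts", rep(sprintf("p%d", 1:8), each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), 8)), collapse = ","),
    paste(seq_len(n) - 1, apply(body, 1, paste, collapse = ","), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}
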