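# Session persistence and the end-to-end report. Sessions are stored as
# plain-text files: DeepLabCut-dialect landmark CSV, wide CSV trace tables,
# TSV event lists, a JSON ground-truth sidecar and a YAML manifest recording
# every parameter that affects results.

fmt17 <- function(x) sprintf("%.17g", x)

write_wide_csv <- function(path, cols) {
  m <- vapply(cols, fmt17, character(length(cols[[1]])))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  lines <- c(paste(names(cols), collapse = ","),
             apply(m, 1, paste, collapse = ","))
  writeLines(lines, path)
}

read_wide_csv <- function(path, expect_cols = NULL) {
  if (!file.exists(path)) {
    pc_stop(sprintf("missing file: %s", path), "pc_missing_file")
  }
  d <- data.table::fread(path, header = TRUE)
  if (!is.null(expect_cols)) {
    missing <- setdiff(expect_cols, names(d))
    if (length(missing) > 0) {
      pc_stop(sprintf("file %s lacks required column(s): %s", basename(path),
                      paste(missing, collapse = ", ")), "pc_schema_error")
    }
  }
  as.data.frame(d)
}

#' Write a simulated session to disk
#'
#' Produces: `landmarks.csv` (DeepLabCut dialect), `cells_raw.csv` /
#' `cells_halo.csv` (wide: time_s plus one column per cell), `speed.csv`,
#' `lick.csv`, `photometry.csv`, `events.tsv` (onset_s, type, value; rewards
#' and stimulation on/offsets), `ground_truth.json`, and `manifest.yaml`
#' (paths, rates, seed, all generator parameters, package version). Numeric
#' values are written with 17 significant digits so a load round-trips
#' bit-exactly.
#'
#' @param session A `pupil_session` from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @param subject_id,group_id Identifiers recorded in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir, subject_id = "sim01",
                          group_id = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_landmarks_dlc(session$landmarks, p("landmarks.csv"))

  cell_names <- sprintf("cell_%03d", seq_len(ncol(session$cells$raw)))
  cells_to_cols <- function(m) {
    cols <- c(list(time_s = session$cells$time_s),
              lapply(seq_len(ncol(m)), function(j) m[, j]))
    names(cols) <- c("time_s", cell_names)
    cols
  }
  write_wide_csv(p("cells_raw.csv"), cells_to_cols(session$cells$raw))
  write_wide_csv(p("cells_halo.csv"), cells_to_cols(session$cells$halo))
  write_wide_csv(p("speed.csv"), list(time_s = session$behavior$time_s,
                                      speed_cmps = session$behavior$speed_cmps))
  write_wide_csv(p("lick.csv"), list(time_s = session$behavior$time_s,
                                     lick = as.numeric(session$behavior$lick)))
  write_wide_csv(p("photometry.csv"),
                 list(time_s = session$photometry$time_s,
                      f_raw = session$photometry$f_raw))

  ev <- data.frame(onset_s = character(0), type = character(0),
                   value = character(0))
  if (length(session$behavior$reward_times_s) > 0) {
    ev <- data.frame(onset_s = fmt17(session$behavior$reward_times_s),
                     type = "reward", value = "1")
  }
  if (nrow(session$behavior$stim_epochs) > 0) {
    se <- session$behavior$stim_epochs
    ev <- rbind(ev,
                data.frame(onset_s = fmt17(se$onset_s), type = "stim_onset",
                           value = fmt17(se$frequency_hz)),
                data.frame(onset_s = fmt17(se$offset_s), type = "stim_offset",
                           value = fmt17(se$frequency_hz)))
  }
  utils::write.table(ev, p("events.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- session$truth
  jsonlite::write_json(list(
    weights = unclass(truth$weights), noise_sd = truth$noise_sd,
    shares = unclass(truth$shares), noise_share = truth$noise_share,
    label_true = truth$label_true, class = truth$class,
    true_kernel_index = truth$true_kernel_index,
    bout_onsets_s = session$behavior$bout_onsets_s,
    bout_offsets_s = session$behavior$bout_offsets_s,
    arousal = session$pupil$arousal
  ), p("ground_truth.json"), digits = I(17), auto_unbox = TRUE)

  manifest <- list(
    subject_id = subject_id, group_id = group_id,
    files = list(landmarks = "landmarks.csv", cells_raw = "cells_raw.csv",
                 cells_halo = "cells_halo.csv", speed = "speed.csv",
                 lick = "lick.csv", photometry = "photometry.csv",
                 events = "events.tsv", ground_truth = "ground_truth.json"),
    pupil_rate_hz = session$config$pupil_rate_hz,
    cell_rate_hz = session$config$cell_rate_hz,
    seed = session$config$seed,
    config = unclass(session$config),
    package_version = as.character(utils::packageVersion("pupilcoding"))
  )
  yaml::write_yaml(manifest, p("manifest.yaml"), precision = 15)
  invisible(p("manifest.yaml"))
}

#' Load a session from disk
#'
#' Reads the manifest and every referenced file, validating that files exist,
#' required columns are present, trace lengths agree with the stated rates,
#' and time columns are strictly increasing. Failures are named (missing
#' file, offending column, or both lengths on a mismatch).
#'
#' @param dir Session directory (containing `manifest.yaml`) or a manifest
#'   path.
#' @return A session bundle mirroring [simulate_session()] output (without
#'   the latent pupil components, which are observables only through the
#'   landmarks), with `manifest` and `manifest_path` attached.
#' @export
load_session <- function(dir) {
  manifest_path <- if (grepl("\\.ya?ml$", dir)) dir else file.path(dir, "manifest.yaml")
  if (!file.exists(manifest_path)) {
    pc_stop(sprintf("missing manifest: %s", manifest_path), "pc_missing_file")
  }
  manifest <- yaml::read_yaml(manifest_path)
  for (field in c("files", "pupil_rate_hz", "cell_rate_hz")) {
    if (is.null(manifest[[field]])) {
      pc_stop(sprintf("manifest lacks required field '%s'", field),
              "pc_schema_error")
    }
  }
  root <- dirname(manifest_path)
  p <- function(key) {
    f <- manifest$files[[key]]
    if (is.null(f)) pc_stop(sprintf("manifest lacks file entry '%s'", key),
                            "pc_schema_error")
    file.path(root, f)
  }
  check_time <- function(t, what) {
    if (is.unsorted(t, strictly = TRUE)) {
      pc_stop(sprintf("%s time column is not strictly increasing", what),
              "pc_schema_error")
    }
  }

  landmarks <- read_landmarks_dlc(p("landmarks"), fps = manifest$pupil_rate_hz)
  speed <- read_wide_csv(p("speed"), c("time_s", "speed_cmps"))
  check_time(speed$time_s, "speed")
  lick <- read_wide_csv(p("lick"), c("time_s", "lick"))
  photometry <- read_wide_csv(p("photometry"), c("time_s", "f_raw"))
  if (nrow(speed) != length(landmarks$time_s)) {
    pc_stop(sprintf("length mismatch: landmarks have %d frames, speed %d samples",
                    length(landmarks$time_s), nrow(speed)), "pc_length_mismatch")
  }
  if (nrow(lick) != nrow(speed)) {
    pc_stop(sprintf("length mismatch: speed has %d samples, lick %d",
                    nrow(speed), nrow(lick)), "pc_length_mismatch")
  }

  raw_df <- read_wide_csv(p("cells_raw"), "time_s")
  halo_df <- read_wide_csv(p("cells_halo"), "time_s")
  if (!identical(names(raw_df), names(halo_df)) ||
      nrow(raw_df) != nrow(halo_df)) {
    pc_stop(sprintf("length mismatch: cell trace tables disagree: raw %d x %d vs halo %d x %d",
                    nrow(raw_df), ncol(raw_df), nrow(halo_df), ncol(halo_df)),
            "pc_length_mismatch")
  }
  check_time(raw_df$time_s, "cell")
  expected_n <- floor(manifest$config$duration_s * manifest$cell_rate_hz)
  if (nrow(raw_df) != expected_n) {
    pc_stop(sprintf("length mismatch: cell traces have %d samples, rate implies %d",
                    nrow(raw_df), expected_n), "pc_length_mismatch")
  }

  ev <- utils::read.delim(p("events"))
  missing <- setdiff(c("onset_s", "type", "value"), names(ev))
  if (length(missing) > 0) {
    pc_stop(sprintf("events.tsv lacks required column(s): %s",
                    paste(missing, collapse = ", ")), "pc_schema_error")
  }
  stim <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                     frequency_hz = numeric(0))
  on <- ev[ev$type == "stim_onset", ]
  off <- ev[ev$type == "stim_offset", ]
  if (nrow(on) > 0) {
    stim <- data.frame(onset_s = as.numeric(on$onset_s),
                       offset_s = as.numeric(off$onset_s),
                       frequency_hz = as.numeric(on$value))
  }

  truth <- NULL
  truth_path <- file.path(root, manifest$files$ground_truth %||% "")
  if (nzchar(manifest$files$ground_truth %||% "") && file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    weights <- as.matrix(tj$weights)
    colnames(weights) <- c("w_pupil", "w_locomotion", "w_reward")
    shares <- as.matrix(tj$shares)
    colnames(shares) <- c("pupil", "locomotion", "reward")
    truth <- structure(list(
      weights = weights, noise_sd = tj$noise_sd,
      shares = shares, noise_share = tj$noise_share,
      label_true = tj$label_true, class = tj$class,
      true_kernel_index = tj$true_kernel_index
    ), class = "ground_truth")
  }

  cell_cols <- setdiff(names(raw_df), "time_s")
  structure(list(
    config = manifest$config,
    behavior = structure(list(
      time_s = speed$time_s, speed_cmps = speed$speed_cmps, lick = lick$lick,
      reward_times_s = as.numeric(ev$onset_s[ev$type == "reward"]),
      stim_epochs = stim,
      bout_onsets_s = if (!is.null(truth)) tj$bout_onsets_s else numeric(0),
      bout_offsets_s = if (!is.null(truth)) tj$bout_offsets_s else numeric(0)
    ), class = "behavior_traces"),
    landmarks = landmarks,
    cells = list(time_s = raw_df$time_s,
                 raw = as.matrix(raw_df[cell_cols]),
                 halo = as.matrix(halo_df[cell_cols])),
    photometry = list(time_s = photometry$time_s, f_raw = photometry$f_raw),
    truth = truth, manifest = manifest, manifest_path = manifest_path
  ), class = "pupil_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis report over a session
#'
#' Executes the requested stages in order -- `pupil` (landmark extraction),
#' `preprocess` (dF/F pipeline + photometry detrending), `encode` (encoding
#' model with variance partitioning), `timeseries` (ON/OFF classification,
#' cross-correlation, coherence) and `bouts` -- failing loudly if a stage's
#' dependency was not run earlier in the same call (no hidden state). The
#' results summary is written as machine-readable JSON embedding the manifest
#' hash and package version; given the same session the JSON is
#' byte-identical across runs.
#'
#' @param session A `pupil_session` (simulated or loaded).
#' @param stages Character vector of stages, in execution order.
#' @param out_dir Output directory for `results.json` and stage tables.
#' @param params Optional overrides: `confidence_threshold`, `r2_threshold`,
#'   `major_cutoff`, `bout_k`, `seed`.
#' @return The results list, invisibly.
#' @export
run_report <- function(session,
                       stages = c("pupil", "preprocess", "encode",
                                  "timeseries", "bouts"),
                       out_dir, params = list()) {
  if (length(stages) == 0) {
    warning("run_report: empty stage list; nothing to do")
    return(invisible(list()))
  }
  known <- c("pupil", "preprocess", "encode", "timeseries", "bouts")
  deps <- list(pupil = character(0), preprocess = character(0),
               encode = c("pupil", "preprocess"),
               timeseries = c("pupil", "preprocess", "encode"),
               bouts = character(0))
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    pc_stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
            "pc_invalid_input")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pr <- function(name, default) params[[name]] %||% default
  cfg <- session$config

  # manifest hash: md5 of the manifest file if the session was loaded,
  # otherwise md5 of the serialised session object
  hash <- if (!is.null(session$manifest_path)) {
    unname(tools::md5sum(session$manifest_path))
  } else {
    tf <- tempfile()
    saveRDS(session, tf, version = 2, compress = FALSE)
    h <- unname(tools::md5sum(tf))
    unlink(tf)
    h
  }

  results <- list(manifest_md5 = hash,
                  package_version = as.character(utils::packageVersion("pupilcoding")),
                  stages = as.list(stages))
  done <- character(0)
  state <- new.env(parent = emptyenv())

  for (stage in stages) {
    missing <- setdiff(deps[[stage]], done)
    if (length(missing) > 0) {
      pc_stop(sprintf("stage '%s' requires earlier stage(s): %s", stage,
                      paste(missing, collapse = ", ")), "pc_missing_stage")
    }
    if (stage == "pupil") {
      trace <- extract_pupil_trace(session$landmarks,
                                   pr("confidence_threshold",
                                      cfg$confidence_threshold %||% 0.9))
      state$pupil <- trace
      utils::write.csv(trace, file.path(out_dir, "pupil.csv"),
                       row.names = FALSE, quote = FALSE)
      results$pupil <- list(
        n_frames = nrow(trace),
        pct_interpolated = 100 * mean(trace$interpolated),
        mean_radius_px = mean(trace$radius_px))
    } else if (stage == "preprocess") {
      state$dff <- preprocess_cells(session$cells$raw, session$cells$halo)
      det <- convex_hull_detrend(session$photometry$f_raw)
      state$photometry <- det$detrended
      results$preprocess <- list(
        n_cells = ncol(state$dff),
        pipeline = as.list(attr(state$dff, "pipeline")))
    } else if (stage == "encode") {
      tc <- session$cells$time_s
      base <- build_predictors(state$pupil, session$behavior$time_s,
                               session$behavior$speed_cmps, tc)
      lick_c <- resample_linear(session$behavior$time_s,
                                as.numeric(session$behavior$lick), tc)
      basis <- make_spline_basis(cfg$cell_rate_hz %||% 5.15)
      rr <- build_reward_regressor(lick_c, basis, state$dff, base)
      X <- if (rr$excluded) base else cbind(base, reward = rr$regressor)
      enc <- encode_cells(state$dff, X,
                          r2_threshold = pr("r2_threshold", 0.05),
                          major_cutoff = pr("major_cutoff", 20))
      state$encoding <- enc
      state$predictors <- X
      utils::write.csv(enc, file.path(out_dir, "encoding.csv"),
                       row.names = FALSE, quote = FALSE)
      kept <- enc[enc$kept, ]
      pie <- table(factor(kept$label,
                          levels = c("pupil", "reward", "both", "other")))
      results$encode <- list(
        chosen_kernel_index = rr$kernel_index,
        n_cells = nrow(enc), n_kept = nrow(kept),
        median_r2_full = stats::median(enc$r2_full),
        label_counts = as.list(stats::setNames(as.integer(pie), names(pie))),
        mean_contrib = as.list(colMeans(
          kept[grep("^contrib_[a-z]+$", names(kept))])))
    } else if (stage == "timeseries") {
      tc <- session$cells$time_s
      kept_idx <- which(state$encoding$kept)
      pupil_c <- zscore(resample_linear(state$pupil$time_s,
                                        state$pupil$radius_px, tc))
      cls <- correlate_and_classify(state$dff[, kept_idx, drop = FALSE],
                                    pupil_c)
      on_idx <- kept_idx[cls$label == "ON"]
      peak_lags <- vapply(on_idx, function(i) {
        cross_correlation(state$dff[, i], pupil_c, max_lag_s = 20,
                          rate_hz = cfg$cell_rate_hz %||% 5.15)$peak_lag_s
      }, numeric(1))
      pupil_p <- resample_linear(state$pupil$time_s, state$pupil$radius_px,
                                 session$photometry$time_s)
      coh <- multitaper_coherence(state$photometry, zscore(pupil_p),
                                  rate_hz = cfg$pupil_rate_hz %||% 20)
      results$timeseries <- list(
        n_on = sum(cls$label == "ON"), n_off = sum(cls$label == "OFF"),
        mean_on_peak_lag_s = if (length(peak_lags)) mean(peak_lags) else NA,
        coherence_below_0p1hz = mean(
          coh$coherence[coh$frequency_hz > 0 & coh$frequency_hz < 0.1]))
    } else if (stage == "bouts") {
      b <- detect_bouts(session$behavior$time_s, session$behavior$speed_cmps)
      part <- run_rest_partition(session$behavior$speed_cmps)
      results$bouts <- list(
        n_bouts = nrow(b$bouts),
        run_fraction = mean(part$run))
      if (nrow(b$profiles) >= pr("bout_k", 4)) {
        cl <- cluster_bouts(b$profiles, k = pr("bout_k", 4),
                            seed = pr("seed", cfg$seed %||% 1))
        results$bouts$cluster_sizes <- as.list(tabulate(cl$cluster,
                                                        pr("bout_k", 4)))
      }
    }
    done <- c(done, stage)
  }

  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
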