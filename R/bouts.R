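# Running-bout detection, k-means bout matching across groups, run/rest
# partition, and thin wrappers for the group-level statistical tests.

#' Detect running bouts
#'
#' Contiguous epochs of speed above `run_threshold` (the 1 cm/s run/rest
#' criterion); gaps shorter than `merge_gap_s` are merged and epochs shorter
#' than `min_duration_s` dropped. Each bout's raw speed profile is extracted
#' over a fixed peri-onset window so profiles are directly comparable across
#' bouts (required by k-means); bouts whose window does not fit inside the
#' trace carry no profile.
#'
#' @param time_s Sample times (uniform rate).
#' @param speed_cmps Running speed, >= 0, cm/s.
#' @param run_threshold Speed threshold in cm/s (default 1).
#' @param min_duration_s Minimum bout duration (default 1 s).
#' @param merge_gap_s Sub-threshold gaps shorter than this are merged
#'   (default 0.5 s).
#' @param profile_window_s Peri-onset window for the profiles (default -2 to
#'   +8 s, which contains both the -2 s baseline and +6 s response probes).
#' @return List of class `running_bouts`: `bouts` data.frame (onset_s,
#'   offset_s, duration_s, has_profile), `profiles` matrix (bout x time, raw
#'   speed), `profile_time_s`, `rate_hz`.
#' @export
detect_bouts <- function(time_s, speed_cmps, run_threshold = 1,
                         min_duration_s = 1, merge_gap_s = 0.5,
                         profile_window_s = c(-2, 8)) {
  stopifnot(length(time_s) == length(speed_cmps), all(speed_cmps >= 0))
  dt <- time_s[2] - time_s[1]
  above <- speed_cmps > run_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start = starts, end = ends, run = r$values)
  runs <- seg[seg$run, c("start", "end"), drop = FALSE]
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- (runs$start[i] - merged$end[nrow(merged)] - 1) * dt
      if (gap < merge_gap_s) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  if (nrow(runs) > 0) {
    dur <- (runs$end - runs$start + 1) * dt
    runs <- runs[dur >= min_duration_s, , drop = FALSE]
  }
  if (nrow(runs) == 0) {
    message("detect_bouts: no bouts detected")
    return(structure(list(
      bouts = data.frame(onset_s = numeric(0), offset_s = numeric(0),
                         duration_s = numeric(0), has_profile = logical(0)),
      profiles = matrix(numeric(0), 0, 0), profile_time_s = numeric(0),
      rate_hz = 1 / dt), class = "running_bouts"))
  }
  rel_idx <- seq(round(profile_window_s[1] / dt),
                 round(profile_window_s[2] / dt))
  has_profile <- runs$start + rel_idx[1] >= 1 &
    runs$start + rel_idx[length(rel_idx)] <= length(speed_cmps)
  profiles <- t(vapply(runs$start[has_profile],
                       function(i) speed_cmps[i + rel_idx],
                       numeric(length(rel_idx))))
  structure(list(
    bouts = data.frame(onset_s = time_s[runs$start],
                       offset_s = time_s[runs$end],
                       duration_s = (runs$end - runs$start + 1) * dt,
                       has_profile = has_profile),
    profiles = profiles, profile_time_s = rel_idx * dt, rate_hz = 1 / dt
  ), class = "running_bouts")
}

# z-score each profile row (a bout's speed profile)
zscore_rows <- function(m) t(apply(m, 1, zscore))

#' K-means clustering of bout profiles
#'
#' Lloyd's algorithm on per-bout z-scored speed profiles, k-means++
#' initialisation under a fixed seed, at most `max_iter` iterations (default
#' 1000) or until centroid convergence. The within-cluster sum of squares is
#' tracked and asserted non-increasing at every iteration. An independent
#' route through `stats::kmeans` is used in the test suite as a cross-check.
#'
#' @param profiles Bout x time matrix of raw speed profiles (z-scored
#'   internally).
#' @param k Number of clusters (1 <= k <= number of bouts).
#' @param seed Integer seed controlling the k-means++ draw.
#' @param max_iter Iteration cap (default 1000).
#' @param tol Centroid convergence tolerance (default 1e-6).
#' @return List with `cluster` (assignments), `centers`, `wss_path`
#'   (within-SS per iteration), `tot_withinss`, `iterations`.
#' @export
cluster_bouts <- function(profiles, k, seed = 1, max_iter = 1000, tol = 1e-6) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (k < 1 || k > n) {
    pc_stop(sprintf("k = %d must be in 1..%d (number of bouts)", k, n),
            "pc_invalid_input")
  }
  Z <- zscore_rows(profiles)
  set.seed(seed)
  centers <- Z[kmeanspp_init(Z, k), , drop = FALSE]
  wss_path <- numeric(0)
  assign_prev <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(Z^2), rep(1, k)) - 2 * Z %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    cl <- max.col(-d2, ties.method = "first")
    wss <- sum(d2[cbind(seq_len(n), cl)])
    if (length(wss_path) > 0 && wss > wss_path[length(wss_path)] + 1e-8) {
      pc_stop("within-cluster SS increased across a Lloyd iteration",
              "pc_internal_error")
    }
    wss_path <- c(wss_path, wss)
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- which(cl == j)
      if (length(members) == 0) {
        # re-seed an empty cluster at the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(n), cl)])
        new_centers[j, ] <- Z[far, ]
      } else {
        new_centers[j, ] <- colMeans(Z[members, , drop = FALSE])
      }
    }
    moved <- max(abs(new_centers - centers))
    centers <- new_centers
    if (all(cl == assign_prev) && moved < tol) break
    assign_prev <- cl
  }
  list(cluster = cl, centers = centers, wss_path = wss_path,
       tot_withinss = wss_path[length(wss_path)], iterations = iter)
}

# k-means++ seeding: returns k row indices of Z
kmeanspp_init <- function(Z, k) {
  n <- nrow(Z)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k == 1) return(idx)
  d2 <- rowSums((Z - matrix(Z[idx[1], ], n, ncol(Z), byrow = TRUE))^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      idx[j] <- sample.int(n, 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums((Z - matrix(Z[idx[j], ], n, ncol(Z),
                                       byrow = TRUE))^2))
  }
  idx
}

#' Match equivalent running bouts across two groups
#'
#' Pools the two groups' bout profiles, clusters the z-scored profiles with
#' [cluster_bouts()], and keeps clusters in which (a) both groups are
#' represented and (b) the groups' mean raw-speed profiles differ by at most
#' `tolerance_cmps` at every time point. The returned per-group bout subsets
#' are matched in locomotion, so downstream pupil comparisons are not
#' confounded by running differences.
#'
#' @param profiles_a,profiles_b Bout x time raw-speed profile matrices for
#'   the two groups (same window and rate).
#' @param k Number of clusters (default 4).
#' @param seed Seed for [cluster_bouts()].
#' @param tolerance_cmps Maximum pointwise difference of the group mean
#'   raw-speed profiles within a qualifying cluster (default 0.5 cm/s).
#' @return List with `index_a`, `index_b` (row indices of matched bouts in
#'   each group), `qualifying_clusters`, `cluster_table` (per-cluster group
#'   counts and mean-speed differences), and the pooled `clustering`.
#' @export
match_equivalent_bouts <- function(profiles_a, profiles_b, k = 4, seed = 1,
                                   tolerance_cmps = 0.5) {
  na <- nrow(profiles_a)
  nb <- nrow(profiles_b)
  if (na == 0 || nb == 0) {
    pc_stop("both groups need at least one bout", "pc_invalid_input")
  }
  pooled <- rbind(profiles_a, profiles_b)
  grp <- rep(c("A", "B"), c(na, nb))
  cl <- cluster_bouts(pooled, k = k, seed = seed)
  tab <- data.frame(cluster = seq_len(k), n_a = 0L, n_b = 0L,
                    max_speed_diff_cmps = NA_real_)
  for (j in seq_len(k)) {
    in_j <- cl$cluster == j
    tab$n_a[j] <- sum(in_j & grp == "A")
    tab$n_b[j] <- sum(in_j & grp == "B")
    if (tab$n_a[j] > 0 && tab$n_b[j] > 0) {
      mean_a <- colMeans(pooled[in_j & grp == "A", , drop = FALSE])
      mean_b <- colMeans(pooled[in_j & grp == "B", , drop = FALSE])
      tab$max_speed_diff_cmps[j] <- max(abs(mean_a - mean_b))
    }
  }
  qual <- which(!is.na(tab$max_speed_diff_cmps) &
                  tab$max_speed_diff_cmps <= tolerance_cmps)
  if (length(qual) == 0) {
    pc_stop(paste0(
      "no cluster has both groups within the speed tolerance; per-cluster ",
      "max |mean speed difference| (cm/s): ",
      paste(sprintf("%d: %.2f", tab$cluster, tab$max_speed_diff_cmps),
            collapse = ", ")), "pc_no_matched_bouts")
  }
  sel <- cl$cluster %in% qual
  list(index_a = which(sel[seq_len(na)]),
       index_b = which(sel[na + seq_len(nb)]),
       qualifying_clusters = qual, cluster_table = tab, clustering = cl)
}

#' Run/rest partition of a session
#'
#' Complementary boolean masks at the binary speed threshold (default
#' 1 cm/s): samples above threshold are "run", the rest "rest".
#'
#' @param speed_cmps Speed trace.
#' @param threshold Threshold in cm/s.
#' @return List with logical `run` and `rest` masks.
#' @export
run_rest_partition <- function(speed_cmps, threshold = 1) {
  run <- speed_cmps > threshold
  list(run = run, rest = !run)
}

#' Group comparison tests
#'
#' Thin wrapper delegating to `stats::t.test` / `stats::wilcox.test`
#' (Mann--Whitney U for unpaired samples), reporting sample sizes, the
#' statistic and the p-value. A paired t-test on identical samples returns
#' statistic 0 with an undefined (NaN) p-value and a warning.
#'
#' @param a,b Numeric samples.
#' @param test `"t"` or `"mannwhitney"`.
#' @param tail `"two.sided"`, `"less"` or `"greater"` (alternative: a > b for
#'   `"greater"`).
#' @param paired Paired test (equal lengths required).
#' @return List with `n`, `statistic`, `p_value`, `test`, `tail`, `paired`.
#' @export
compare_groups <- function(a, b, test = c("t", "mannwhitney"),
                           tail = c("two.sided", "less", "greater"),
                           paired = FALSE) {
  test <- match.arg(test)
  tail <- match.arg(tail)
  if (length(a) < 2 || length(b) < 2) {
    pc_stop("each group needs at least 2 observations", "pc_invalid_input")
  }
  if (paired && length(a) != length(b)) {
    pc_stop("paired test requires equal lengths", "pc_invalid_input")
  }
  if (test == "t" && paired && stats::sd(a - b) == 0) {
    warning("zero-variance paired differences: t = 0, p undefined")
    return(list(n = c(length(a), length(b)), statistic = 0, p_value = NaN,
                test = test, tail = tail, paired = paired))
  }
  fit <- if (test == "t") {
    stats::t.test(a, b, alternative = tail, paired = paired)
  } else {
    stats::wilcox.test(a, b, alternative = tail, paired = paired,
                       exact = FALSE)
  }
  list(n = c(length(a), length(b)), statistic = unname(fit$statistic),
       p_value = fit$p.value, test = test, tail = tail, paired = paired)
}

#' Simulate an ablation-style two-group bout scenario
#'
#' Builds a synthetic two-group experiment in which both groups share the
#' same running-bout statistics but differ in baseline pupil size (the
#' orexin-ablated group dilates less), mirroring the bout-matched comparison
#' design: per mouse, a running session is generated, the pupil baseline is
#' shifted by the group effect, and bout-aligned pupil baselines are taken at
#' -2 s from run onset.
#'
#' @param n_a,n_b Mice per group (defaults 8 control, 7 ablated).
#' @param duration_s Per-mouse session length (default 240 s).
#' @param baseline_diff_px Group difference in baseline pupil radius. The
#'   default (4 px) is about 1.8x the per-mouse baseline sd -- between-mouse
#'   spread (1.5 px) plus residual arousal noise on bout-sampled baselines
#'   (~3.6 px per bout, autocorrelated across bouts, ~1.6 px after averaging
#'   a mouse's bouts) -- giving the one-tailed two-sample t-test roughly 95%
#'   power at these group sizes.
#' @param between_sd_px Between-mouse sd of baseline radius (default 1.5 px).
#' @param seed Integer seed.
#' @return List with per-group bout profile matrices (`profiles_a/b`),
#'   aligned per-bout vectors `mouse_a/b` (mouse index) and `baseline_a/b`
#'   (pupil radius at -2 s from each bout onset, px), and `n_a`, `n_b`.
#' @export
simulate_dtr_scenario <- function(n_a = 8, n_b = 7, duration_s = 240,
                                  baseline_diff_px = 4,
                                  between_sd_px = 1.5, seed = 1) {
  set.seed(seed)
  n_mice <- n_a + n_b
  mouse_seed <- sample.int(2^20, n_mice)
  base_mu <- c(rep(30, n_a), rep(30 - baseline_diff_px, n_b))
  base_px <- stats::rnorm(n_mice, base_mu, between_sd_px)
  profiles <- vector("list", n_mice)
  baselines <- vector("list", n_mice)
  for (i in seq_len(n_mice)) {
    cfg <- simulation_config(duration_s = duration_s, n_rewards = 0,
                             run_bout_rate = 4, blink_rate_hz = 0,
                             pupil_baseline_px = base_px[i],
                             seed = mouse_seed[i])
    beh <- simulate_behavior(cfg)
    pup <- simulate_pupil(beh, cfg)
    b <- detect_bouts(beh$time_s, beh$speed_cmps)
    profiles[[i]] <- b$profiles
    onsets <- b$bouts$onset_s[b$bouts$has_profile]
    al <- align_to_events(pup$time_s, pup$radius_px, onsets,
                          window_s = c(-2, 8),
                          baseline_window_s = c(-2, -2),
                          response_window_s = c(6, 6))
    baselines[[i]] <- al$baseline
  }
  is_a <- seq_len(n_a)
  nb_a <- vapply(profiles[is_a], nrow, integer(1))
  nb_b <- vapply(profiles[-is_a], nrow, integer(1))
  list(profiles_a = do.call(rbind, profiles[is_a]),
       profiles_b = do.call(rbind, profiles[-is_a]),
       mouse_a = rep(seq_len(n_a), nb_a),
       mouse_b = rep(seq_len(n_b), nb_b),
       baseline_a = unlist(baselines[is_a]),
       baseline_b = unlist(baselines[-is_a]),
       n_a = n_a, n_b = n_b)
}
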