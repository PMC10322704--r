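test_that("bout detection handles empty, rectangular, mergeable and short epochs", {
  t <- seq(0, 59.95, by = 0.05)
  expect_message(b0 <- detect_bouts(t, rep(0, length(t))), "no bouts")
  expect_equal(nrow(b0$bouts), 0)

  speed <- rep(0, length(t))
  speed[t >= 20 & t < 25] <- 10
  b1 <- detect_bouts(t, speed)
  expect_equal(nrow(b1$bouts), 1)
  expect_equal(b1$bouts$onset_s, 20)
  expect_equal(b1$bouts$offset_s, 24.95)

  # a 0.3 s dip is merged; an isolated 0.5 s blip is dropped
  speed2 <- speed
  speed2[t >= 22 & t < 22.3] <- 0
  speed2[t >= 40 & t < 40.5] <- 8
  b2 <- detect_bouts(t, speed2)
  expect_equal(nrow(b2$bouts), 1)
  expect_equal(b2$bouts$onset_s, 20)
})

test_that("detected onsets match generative switch times to the sample", {
  cfg <- simulation_config(duration_s = 600, n_rewards = 0,
                           run_bout_rate = 3, seed = 33)
  beh <- simulate_behavior(cfg)
  b <- detect_bouts(beh$time_s, beh$speed_cmps)
  expect_equal(nrow(b$bouts), length(beh$bout_onsets_s))
  expect_lte(max(abs(b$bouts$onset_s - beh$bout_onsets_s)), 1 / 20)
  # every bout lies inside the run mask
  part <- run_rest_partition(beh$speed_cmps)
  for (i in seq_len(nrow(b$bouts))) {
    idx <- which(beh$time_s >= b$bouts$onset_s[i] &
                   beh$time_s <= b$bouts$offset_s[i])
    expect_true(all(part$run[idx]))
  }
})

test_that("k-means: k = 1 centroid is the mean profile; duplicates co-assign", {
  set.seed(34)
  prof <- matrix(rnorm(20 * 50), 20, 50) + 3
  cl <- cluster_bouts(prof, k = 1, seed = 1)
  Z <- t(apply(prof, 1, zscore))
  expect_equal(as.numeric(cl$centers), colMeans(Z), tolerance = 1e-12)

  dup <- rbind(prof, prof[3, , drop = FALSE])
  cl2 <- cluster_bouts(dup, k = 3, seed = 2)
  expect_equal(cl2$cluster[21], cl2$cluster[3])
  # within-cluster SS never increases across Lloyd iterations
  expect_true(all(diff(cl2$wss_path) <= 1e-8))
})

test_that("two well-separated bout shapes are perfectly recovered (ARI = 1)", {
  set.seed(35)
  tpts <- seq(-2, 8, by = 0.1)
  early <- exp(-(tpts - 1)^2)      # early peak
  late <- exp(-(tpts - 6)^2)       # late peak
  truth <- rep(1:2, each = 25)
  prof <- rbind(
    matrix(rep(early, 25), 25, byrow = TRUE),
    matrix(rep(late, 25), 25, byrow = TRUE)
  ) + matrix(rnorm(50 * length(tpts), sd = 0.05), 50)
  cl <- cluster_bouts(prof, k = 2, seed = 3)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)
})

test_that("this Lloyd implementation agrees with stats::kmeans", {
  set.seed(36)
  prof <- rbind(matrix(rnorm(60, 0), 12, 5), matrix(rnorm(40, 5), 8, 5))
  Z <- t(apply(prof, 1, zscore))
  ours <- cluster_bouts(prof, k = 2, seed = 4)
  ref <- stats::kmeans(Z, centers = ours$centers, algorithm = "Lloyd",
                       iter.max = 1000)
  expect_equal(ours$tot_withinss, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(unname(table(ours$cluster)), unname(table(ref$cluster)))
})

test_that("matching: exchangeable groups qualify, disjoint speeds fail", {
  set.seed(37)
  shape <- exp(-(seq(-2, 8, by = 0.1) - 3)^2 / 4)
  make <- function(n, scale) {
    t(vapply(seq_len(n),
             function(i) scale * shape * runif(1, 0.95, 1.05) +
               abs(rnorm(length(shape), sd = 0.02)),
             numeric(length(shape))))
  }
  a <- make(30, 5)
  b <- make(30, 5)
  m <- match_equivalent_bouts(a, b, k = 2, seed = 5)
  expect_gt(length(m$index_a), 0)
  expect_gt(length(m$index_b), 0)   # never one-group-only
  tab <- m$cluster_table[m$qualifying_clusters, ]
  expect_true(all(tab$max_speed_diff_cmps <= 0.5))

  expect_error(match_equivalent_bouts(a, make(30, 10), k = 2, seed = 5),
               class = "pc_no_matched_bouts")
})

test_that("run/rest partition is complementary at the 1 cm/s threshold", {
  expect_true(all(run_rest_partition(rep(0, 10))$rest))
  expect_true(all(run_rest_partition(rep(5, 10))$run))
  alt <- rep(c(0, 5), 10)
  part <- run_rest_partition(alt)
  expect_equal(part$run, alt == 5)
  expect_equal(part$rest, !part$run)
})

test_that("group tests delegate correctly and handle degenerate input", {
  mw <- compare_groups(c(1, 2, 3), c(4, 5, 6), test = "mannwhitney",
                       tail = "two.sided")
  expect_equal(mw$statistic, 0)  # complete separation

  expect_warning(tt <- compare_groups(c(1, 2, 3), c(1, 2, 3), test = "t",
                                      paired = TRUE),
                 "zero-variance")
  expect_equal(tt$statistic, 0)
  expect_true(is.nan(tt$p_value))
  expect_error(compare_groups(1, c(1, 2)), class = "pc_invalid_input")
})

test_that("one-tailed t-test power matches the analytic closed form", {
  set.seed(38)
  n <- 15
  delta <- 1
  m <- 400
  hits <- vapply(seq_len(m), function(i) {
    compare_groups(rnorm(n, delta), rnorm(n), test = "t",
                   tail = "greater")$p_value < 0.05
  }, logical(1))
  ana <- stats::power.t.test(n = n, delta = delta, sd = 1,
                             sig.level = 0.05, type = "two.sample",
                             alternative = "one.sided")$power
  mc_se <- sqrt(ana * (1 - ana) / m)
  expect_lt(abs(mean(hits) - ana), 4 * mc_se)
})
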