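#!/usr/bin/env Rscript
# Ablation-style group comparison: equivalent running bouts matched by
# k-means on z-scored bout profiles, then bout-aligned pupil baselines
# compared across groups (one-tailed t-test), with locomotion controlled.

library(pupilcoding)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

sc <- simulate_dtr_scenario(seed = seed)
m <- match_equivalent_bouts(sc$profiles_a, sc$profiles_b, k = 3, seed = 1)
tab <- m$cluster_table
write.csv(tab, "results/bout_clusters.csv", row.names = FALSE, quote = FALSE)
cat(sprintf("Matched %d + %d bouts in %d qualifying cluster(s); max mean-speed difference %.2f cm/s\n",
            length(m$index_a), length(m$index_b),
            length(m$qualifying_clusters),
            max(tab$max_speed_diff_cmps[m$qualifying_clusters])))

a <- tapply(sc$baseline_a[m$index_a], sc$mouse_a[m$index_a], mean)
b <- tapply(sc$baseline_b[m$index_b], sc$mouse_b[m$index_b], mean)
tt <- compare_groups(a, b, test = "t", tail = "greater")
cat(sprintf("Baseline pupil at -2 s: control %.1f px vs ablated %.1f px; one-tailed t = %.2f, p = %.3g (n = %d vs %d mice)\n",
            mean(a), mean(b), tt$statistic, tt$p_value, tt$n[1], tt$n[2]))
write.csv(data.frame(group = rep(c("control", "ablated"),
                                 c(length(a), length(b))),
                     baseline_px = c(a, b)),
          "results/bout_baselines.csv", row.names = FALSE, quote = FALSE)
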