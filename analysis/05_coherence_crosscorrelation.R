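#!/usr/bin/env Rscript
# Pupil ON/OFF classification, lagged cross-correlation of ON cells, and
# multitaper coherence (7 DPSS tapers, adaptive weighting) between the
# detrended photometry trace and pupil size.

library(pupilcoding)
session <- load_session("results/session")
trace <- read.csv("results/pupil.csv")
dff <- as.matrix(read.csv("results/cells_dff.csv")[, -1])
enc <- read.csv("results/encoding.csv")
tc <- session$cells$time_s

pupz <- zscore(resample_linear(trace$time_s, trace$radius_px, tc))
kept <- which(enc$kept)
cls <- correlate_and_classify(dff[, kept, drop = FALSE], pupz)
write.csv(cls, "results/on_off_cells.csv", row.names = FALSE, quote = FALSE)
cat(sprintf("Pupil ON: %d cells, OFF: %d cells (of %d kept)\n",
            sum(cls$label == "ON"), sum(cls$label == "OFF"), length(kept)))

on_cells <- kept[cls$label == "ON"]
cc_rows <- lapply(on_cells, function(i) {
  cc <- cross_correlation(dff[, i], pupz, max_lag_s = 20,
                          rate_hz = session$config$cell_rate_hz)
  data.frame(cell_id = i, lag_s = cc$lag_s, cc = cc$cc)
})
cc_tidy <- do.call(rbind, cc_rows)
write.csv(cc_tidy, "results/crosscorrelation.csv", row.names = FALSE,
          quote = FALSE)
mean_cc <- aggregate(cc ~ lag_s, cc_tidy, mean)
cat(sprintf("Mean ON-cell cross-correlation peaks at %+.2f s\n",
            mean_cc$lag_s[which.max(mean_cc$cc)]))

det <- read.csv("results/photometry_detrended.csv")
pup20 <- zscore(resample_linear(trace$time_s, trace$radius_px, det$time_s))
coh <- multitaper_coherence(det$detrended, pup20,
                            rate_hz = session$config$pupil_rate_hz)
write.csv(data.frame(frequency_hz = coh$frequency_hz,
                     coherence = coh$coherence),
          "results/coherence.csv", row.names = FALSE, quote = FALSE)
low <- coh$frequency_hz > 0 & coh$frequency_hz < 0.1
cat(sprintf("Photometry-pupil coherence below 0.1 Hz: %.2f (bandwidth %.3f Hz)\n",
            mean(coh$coherence[low]), coh$bandwidth_hz))
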