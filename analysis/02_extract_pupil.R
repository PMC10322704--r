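#!/usr/bin/env Rscript
# Landmark CSV -> pupil radius/area trace with confidence-gated interpolation.

library(pupilcoding)
session <- load_session("results/session")
trace <- extract_pupil_trace(session$landmarks,
                             session$config$confidence_threshold)
write.csv(trace, "results/pupil.csv", row.names = FALSE, quote = FALSE)

cat(sprintf("Extracted %d frames; %.2f%% interpolated (blinks/low confidence)\n",
            nrow(trace), 100 * mean(trace$interpolated)))
cat(sprintf("Radius %.1f-%.1f px (mean %.1f px)\n",
            min(trace$radius_px), max(trace$radius_px),
            mean(trace$radius_px)))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(trace[trace$time_s < 300, ],
              aes(time_s, radius_px, colour = interpolated)) +
    geom_point(size = 0.2) +
    scale_colour_manual(values = c("black", "red")) +
    labs(x = "time (s)", y = "pupil radius (px)",
         title = "Extracted pupil trace (first 5 min)") +
    theme_minimal()
  ggsave("results/pupil_trace.png", p, width = 9, height = 3, dpi = 120)
}
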