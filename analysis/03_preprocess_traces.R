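#!/usr/bin/env Rscript
# Neuropil-corrected, smoothed, z-scored dF/F for every cell; convex-hull
# detrended photometry.

library(pupilcoding)
session <- load_session("results/session")

dff <- preprocess_cells(session$cells$raw, session$cells$halo)
out <- data.frame(time_s = session$cells$time_s, dff)
write.csv(out, "results/cells_dff.csv", row.names = FALSE, quote = FALSE)

det <- convex_hull_detrend(session$photometry$f_raw)
write.csv(data.frame(time_s = session$photometry$time_s,
                     detrended = det$detrended,
                     template = det$template),
          "results/photometry_detrended.csv", row.names = FALSE, quote = FALSE)

cat(sprintf("Processed %d cells (%s)\n", ncol(dff),
            paste(attr(dff, "pipeline"), collapse = " -> ")))
cat(sprintf("Photometry detrended: template spans %.2f of the raw range\n",
            diff(range(det$template)) / diff(range(session$photometry$f_raw))))
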