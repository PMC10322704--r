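#!/usr/bin/env Rscript
# End-to-end deterministic report over the stored session.

library(pupilcoding)
session <- load_session("results/session")
res <- run_report(session, out_dir = "results/report")
cat("Report written to results/report/results.json\n")
cat(sprintf("  stages: %s\n", paste(unlist(res$stages), collapse = ", ")))
cat(sprintf("  kept cells: %d; label counts: %s\n", res$encode$n_kept,
            paste(names(res$encode$label_counts),
                  unlist(res$encode$label_counts), collapse = ", ")))
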