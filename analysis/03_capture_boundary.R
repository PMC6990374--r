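#!/usr/bin/env Rscript
# S1-S2 capture boundary on healthy tissue: decrement the coupling
# interval by 10 ms from 500 ms until the premature beat fails to
# propagate. Writes results/capture_boundary.csv.
suppressPackageStartupMessages(library(infarctsim))
dir.create("results", showWarnings = FALSE)

res <- find_min_capture_ci(strip_template())
print(res$tested)
cat(sprintf("minimal capturing coupling interval: %d ms (first failure %d ms)\n",
            res$min_ci, res$boundary_fail_ci))
write.csv(res$tested, "results/capture_boundary.csv", row.names = FALSE)
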