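#!/usr/bin/env Rscript
# Match components across the two condition decompositions by topography
# correlation (threshold 0.85, up to 3 per condition per cluster, 40
# template orderings). Writes results/run/ic_pairs.json.

source(file.path("analysis", "config.R"))

res <- run_pipeline(cfg, out_dir = run_dir, stages = "corrmap")
pairs <- res$results$corrmap

cat(sprintf("matched pairs: %d\n", nrow(pairs)))
print(pairs, row.names = FALSE)
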