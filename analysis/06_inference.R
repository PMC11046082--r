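#!/usr/bin/env Rscript
# Group-level cluster-based permutation inference against chance for each
# matched pair: 1-D on the diagonal AUC and 2-D on the generalization
# matrix (sign-flip null, 500 permutations). Writes results/run/clusters.json.

source(file.path("analysis", "config.R"))

res <- run_pipeline(cfg, out_dir = run_dir, stages = "infer")
inf <- res$results$infer
times <- epoch_times()

for (pn in names(inf)) {
  sig <- Filter(function(cl) cl$p < 0.05, inf[[pn]]$diag$clusters)
  if (length(sig)) {
    top <- sig[[1]]
    cat(sprintf("%s: %d significant diagonal cluster(s); top %+.0f..%+.0f ms (p = %.4g)\n",
                pn, length(sig), times[min(top$cells)], times[max(top$cells)],
                top$p))
  } else {
    cat(sprintf("%s: no significant diagonal cluster\n", pn))
  }
  sig2 <- Filter(function(cl) cl$p < 0.05, inf[[pn]]$tg$clusters)
  cat(sprintf("        %d significant generalization cluster(s)\n",
              length(sig2)))
}
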