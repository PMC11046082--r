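#!/usr/bin/env Rscript
# Leave-one-out neural-network regression from each pair's windowed mean
# AUC to the per-subject SSRT congruency effect, with pairwise RMSE
# comparisons across pairs. Writes results/run/brainbehavior.json.

source(file.path("analysis", "config.R"))

res <- run_pipeline(cfg, out_dir = run_dir, stages = "brainbehavior")
bb <- res$results$brainbehavior

for (pn in names(bb$fits)) {
  f <- bb$fits[[pn]]
  cat(sprintf("%s: LOO RMSE %.2f ms (95%% CI %.2f-%.2f); target SD %.2f ms\n",
              pn, f$rmse, f$rmse_ci[1], f$rmse_ci[2], sd(bb$targets)))
}
if (!is.null(bb$comparisons)) {
  cat(sprintf("pairwise RMSE comparisons: min p = %.3f (all > .05: %s)\n",
              min(bb$comparisons$p), all(bb$comparisons$p > 0.05)))
}
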