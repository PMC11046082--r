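#!/usr/bin/env Rscript
# Group independent-component decomposition of the Stop-trial epochs,
# fitted separately for the congruent and incongruent conditions
# (PCA retention 98%, at most 20 components, fixed-point ICA).

source(file.path("analysis", "config.R"))

res <- run_pipeline(cfg, out_dir = run_dir, stages = "gica")
g <- res$results$gica

for (cc in c("congruent", "incongruent")) {
  fit <- g[[cc]]
  frac <- cumsum(fit$eigenvalues)[fit$n_retained] / sum(fit$eigenvalues)
  cat(sprintf("%-12s %d components (%.1f%% variance), %d ICA iterations\n",
              cc, fit$n_retained, 100 * frac, fit$iterations))
}
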