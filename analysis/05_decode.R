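#!/usr/bin/env Rscript
# Per-subject, per-pair decoding of congruent vs. incongruent Stop trials
# on the back-projected component data: time-resolved AUC and the full
# temporal-generalization matrix (5-fold CV, balanced classes, linear
# maximum-margin classifier on the 60 channel amplitudes).

source(file.path("analysis", "config.R"))

res <- run_pipeline(cfg, out_dir = run_dir, stages = "decode")
dec <- res$results$decode

for (pn in names(dec)) {
  diag_mat <- do.call(rbind, lapply(dec[[pn]], `[[`, "auc_diag"))
  grand <- colMeans(diag_mat)
  cat(sprintf("%s: grand-mean AUC %.3f, peak %.3f at %+.0f ms\n",
              pn, mean(grand), max(grand), epoch_times()[which.max(grand)]))
}
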