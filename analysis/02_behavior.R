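#!/usr/bin/env Rscript
# Behavioral analysis: per-subject summaries, exclusion report, and the
# paired congruency contrasts (go RT, SSRT, stopping probability).
#
# Writes results/run/behavior_summary.tsv, exclusions.tsv, contrasts.json.

source(file.path("analysis", "config.R"))

res <- run_pipeline(cfg, out_dir = run_dir, stages = "behavior")
beh <- res$results$behavior

cat(sprintf("included subjects: %d of %d\n", length(beh$kept),
            nrow(beh$exclusions)))
for (ct in beh$contrasts)
  cat(sprintf("%-15s congruent %.1f vs incongruent %.1f (V = %s, p = %.4g)\n",
              ct$measure, ct$mean_congruent, ct$mean_incongruent,
              format(ct$statistic), ct$p))
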