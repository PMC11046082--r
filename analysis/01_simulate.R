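#!/usr/bin/env Rscript
# Simulate the behavioral cohort and its Stop-trial EEG epochs.
#
# Writes results/run/trial_logs.tsv and caches the epochs for the later
# stages. Prints the realized trial counts and stopping probability so
# the staircase behavior is visible at a glance.

source(file.path("analysis", "config.R"))

res <- run_pipeline(cfg, out_dir = run_dir, stages = "simulate")
logs <- res$results$simulate$logs

log1 <- logs[[1]]
cat(sprintf("subjects: %d; trials/session: %d (%d Go / %d Stop)\n",
            length(logs), nrow(log1), sum(log1$is_stop == 0),
            sum(log1$is_stop == 1)))
p_resp <- vapply(logs, function(l)
  mean(l$outcome[l$is_stop == 1] == "failed_stop"), numeric(1))
cat(sprintf("p(respond|stop): mean %.3f, range %.3f-%.3f\n",
            mean(p_resp), min(p_resp), max(p_resp)))
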