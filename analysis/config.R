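# Shared configuration for the numbered analysis drivers.
#
# The cohort is scaled to 16 subjects and 3 blocks (36 Stop trials per
# condition) so the full chain runs in a few minutes on one CPU while
# keeping every stage's behavior qualitatively at study scale; the
# session design, race parameters, decomposition and matching settings
# are the study defaults.

library(conflictstop)

run_dir <- file.path("results", "run")
cfg <- pipeline_config(
  seed = 20260919L,
  n_subjects = 16L,
  design = task_design(n_blocks = 3L),
  n_perm = 500L,
  n_boot = 1000L
)
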