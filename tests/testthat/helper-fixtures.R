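# Shared fixtures, built lazily and cached for the whole test run.
.fix <- new.env(parent = emptyenv())

# Small emulated study: 6 subjects, 2 blocks (24 Stop trials per
# condition), default ground truth, both decompositions and the matched
# pairs. Used by the corrmap / decode / pipeline-adjacent tests.
small_study <- function() {
  if (!is.null(.fix$small)) return(.fix$small)
  design <- task_design(n_blocks = 2L)
  logs <- simulate_cohort(6L, design = design, seed = 101L)
  truth <- ground_truth(n_subjects = 6L, seed = 202L)
  epochs <- generate_group_eeg(logs, truth)
  fits <- suppressWarnings(list(
    congruent = fit_group_ica(concatenate_epochs(epochs, "congruent"),
                              seed = 11L),
    incongruent = fit_group_ica(concatenate_epochs(epochs, "incongruent"),
                                seed = 12L)))
  pairs <- match_components(fits$congruent, fits$incongruent, seed = 5L)
  .fix$small <- list(design = design, logs = logs, truth = truth,
                     epochs = epochs, gica = fits, pairs = pairs)
  .fix$small
}

# Single-subject rank-1 tensors with a d = 1 condition effect in the
# 85-245 ms window and no baseline/noise: the closed-form AUC oracle
# construction.
rank1_effect_epochs <- function(n_subjects = 2L, effect = 1,
                                n_blocks = 5L, seed = 303L) {
  key <- paste0("rank1_", n_subjects, "_", effect, "_", n_blocks)
  if (!is.null(.fix[[key]])) return(.fix[[key]])
  logs <- simulate_cohort(n_subjects, design = task_design(n_blocks = n_blocks),
                          seed = seed)
  src <- list(source_spec(smooth_topography(c(0, -0.75)), c(85, 245),
                          effect_size = effect,
                          baseline_erp = rep(0, 307)))
  truth <- ground_truth(sources = src, n_subjects = n_subjects,
                        noise_sd = 0, trial_gain_sd = 0, seed = seed + 1L)
  .fix[[key]] <- generate_group_eeg(logs, truth)
  .fix[[key]]
}

# Toy 4-trial log covering each outcome type once (plus schema columns).
toy_log <- function() {
  data.frame(
    block = 1L, trial = 1:4,
    condition = c("congruent", "incongruent", "congruent", "incongruent"),
    position = c("left", "right", "left", "right"),
    is_stop = c(0L, 0L, 1L, 1L),
    ssd_ms = c(NA, NA, 250, 300),
    rt_ms = c(480, NA, NA, 430),
    response = c("left", "none", "none", "left"),
    outcome = c("hit", "miss", "correct_rejection", "failed_stop"),
    stringsAsFactors = FALSE)
}

window_samples <- function(lo = 85, hi = 245) {
  which(epoch_times() >= lo & epoch_times() <= hi)
}
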