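#' Epoch time axis
#'
#' 307 samples at 256 Hz covering \code{[-200, 1000)} ms around the
#' epoching event (half-open grid: \code{t_i = -200 + i * 1000/256},
#' i = 0..306, last sample at about +995 ms).
#'
#' @return numeric vector of length 307, in ms.
#' @export
epoch_times <- function() -200 + (0:306) * (1000 / 256)

#' Synthetic 60-channel electrode layout
#'
#' 2-D positions for 60 equidistant-style electrodes arranged on
#' concentric rings of a unit disc. Used only to build smooth synthetic
#' scalp topographies; no anatomical head model is implied.
#'
#' @return a 60 x 2 matrix of x/y positions with channel labels E01..E60.
#' @export
electrode_layout <- function() {
  counts <- c(1L, 8L, 14L, 17L, 20L)
  radii <- c(0, 0.25, 0.5, 0.75, 0.98)
  xy <- do.call(rbind, lapply(seq_along(counts), function(i) {
    k <- counts[i]
    th <- 2 * pi * (seq_len(k) - 1) / k + 0.2 * i
    cbind(radii[i] * cos(th), radii[i] * sin(th))
  }))
  rownames(xy) <- sprintf("E%02d", seq_len(nrow(xy)))
  colnames(xy) <- c("x", "y")
  xy
}

#' Smooth unit-norm topography
#'
#' Gaussian bump centred at \code{center} on the synthetic layout,
#' channel-demeaned (average-reference-like) and normalized to unit
#' Euclidean norm.
#'
#' @param center length-2 x/y position on the unit disc.
#' @param width Gaussian width on the layout scale.
#' @param layout channel positions, see \code{\link{electrode_layout}}.
#' @return length-60 unit-norm numeric vector.
#' @export
smooth_topography <- function(center, width = 0.45, layout = electrode_layout()) {
  d2 <- (layout[, 1] - center[1])^2 + (layout[, 2] - center[2])^2
  v <- exp(-d2 / (2 * width^2))
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

#' Ground-truth source specification
#'
#' One latent source of the synthetic EEG: a fixed unit-norm spatial
#' topography over the 60 channels, a shared baseline ERP waveform, and a
#' condition effect confined to a time window. Inside the window each
#' trial receives a standardized amplitude (mean-zero, unit-SD across the
#' trials of a condition) shifted by \code{-effect_size/2} for congruent
#' and \code{+effect_size/2} for incongruent trials, so
#' \code{effect_size} is the standardized incongruent-minus-congruent
#' activation difference and the ideal pointwise discrimination AUC inside
#' the window is \code{pnorm(effect_size / sqrt(2))}.
#'
#' @param topography numeric length-60 unit-norm vector.
#' @param window_ms length-2 numeric, start/end of the condition-effect
#'   window in ms relative to epoch zero.
#' @param effect_size standardized mean activation difference
#'   (incongruent - congruent).
#' @param baseline_erp length-307 waveform added to every trial's source
#'   activation (drives the non-Gaussian temporal structure that makes the
#'   source identifiable by ICA).
#' @return an object of class \code{source_spec}.
#' @export
source_spec <- function(topography, window_ms, effect_size = 0.5,
                        baseline_erp = numeric(307)) {
  topography <- as.numeric(topography)
  if (length(topography) != 60L)
    stop("source_spec: topography must have 60 channels")
  nrm <- sqrt(sum(topography^2))
  if (abs(nrm - 1) > 1e-6) topography <- topography / nrm
  times <- epoch_times()
  if (length(window_ms) != 2L || window_ms[1] >= window_ms[2] ||
      window_ms[1] < times[1] || window_ms[2] > times[length(times)])
    stop("source_spec: window_ms must be an increasing pair within the epoch")
  if (length(baseline_erp) != length(times))
    stop("source_spec: baseline_erp must have ", length(times), " samples")
  structure(list(topography = topography, window_ms = as.numeric(window_ms),
                 effect_size = effect_size,
                 baseline_erp = as.numeric(baseline_erp)),
            class = "source_spec")
}

# Gaussian ERP bump centred in the window.
erp_bump <- function(window_ms, amplitude = 3, times = epoch_times()) {
  ctr <- mean(window_ms)
  sdv <- diff(window_ms) / 4
  amplitude * exp(-(times - ctr)^2 / (2 * sdv^2))
}

#' Default ground-truth sources
#'
#' Four sources whose effect windows emulate the decoding windows of the
#' modelled study: an early posterior source (85-245 ms, negative ERP), a
#' sustained central source (300-700 ms, biphasic ERP), and two
#' mid-latency sources (100-450 ms and 250-400 ms, positive ERPs). The
#' baseline waveforms are mutually orthogonalized over the epoch
#' (Gram-Schmidt, preserving each original waveform's RMS amplitude) so
#' that the latent source activations are uncorrelated, as the
#' independent-component model assumes.
#'
#' @param effect_size standardized condition effect shared by all sources.
#' @return list of \code{\link{source_spec}} objects.
#' @export
default_sources <- function(effect_size = 0.5) {
  layout <- electrode_layout()
  centers <- list(c(0, -0.75), c(0, 0.35), c(-0.6, 0.1), c(0.6, 0.1))
  windows <- list(c(85, 245), c(300, 700), c(100, 450), c(250, 400))
  amps <- c(-9, 9, 7.5, 7.5)
  times <- epoch_times()
  erps <- matrix(0, length(times), 4L)
  for (k in 1:4) {
    erp <- erp_bump(windows[[k]], amps[k], times)
    if (k == 2L)  # biphasic: negative lobe before the positive bump
      erp <- erp - erp_bump(c(0, 300), 6, times)
    erps[, k] <- erp
  }
  # orthogonalize, keeping each waveform's RMS
  for (k in 2:4) {
    rms <- sqrt(mean(erps[, k]^2))
    for (j in seq_len(k - 1L))
      erps[, k] <- erps[, k] -
        sum(erps[, k] * erps[, j]) / sum(erps[, j]^2) * erps[, j]
    erps[, k] <- erps[, k] * rms / sqrt(mean(erps[, k]^2))
  }
  lapply(1:4, function(k)
    source_spec(smooth_topography(centers[[k]], layout = layout),
                windows[[k]], effect_size, erps[, k]))
}

#' Ground truth for the synthetic EEG generator
#'
#' @param race a \code{\link{race_params}} object (behavioral generator).
#' @param sources list of \code{\link{source_spec}} objects.
#' @param n_subjects number of subjects (>= 2).
#' @param noise_sd Gaussian sensor noise SD, in the same arbitrary units
#'   as the source activations.
#' @param subject_jitter SD of the per-channel perturbation applied to the
#'   group topography for each subject (re-normalized afterwards).
#' @param trial_gain_sd SD of the per-trial multiplicative gain on each
#'   source's baseline ERP (empirically centered within subject and
#'   condition); models trial-to-trial amplitude variability and gives
#'   each source independent trial-level variance.
#' @param seed integer seed for all EEG randomness.
#' @return an object of class \code{ground_truth}.
#' @export
ground_truth <- function(race = race_params(), sources = default_sources(),
                         n_subjects = 53L, noise_sd = 1, subject_jitter = 0.01,
                         trial_gain_sd = 1, seed = 1L) {
  if (n_subjects < 2L) stop("ground_truth: n_subjects must be >= 2")
  if (noise_sd < 0) stop("ground_truth: noise_sd must be >= 0")
  if (!all(vapply(sources, inherits, logical(1), "source_spec")))
    stop("ground_truth: sources must be source_spec objects")
  structure(list(race = race, sources = sources,
                 n_subjects = as.integer(n_subjects), noise_sd = noise_sd,
                 subject_jitter = subject_jitter,
                 trial_gain_sd = trial_gain_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate group EEG epochs for Stop trials
#'
#' Builds per-subject, per-condition epoch arrays from the trial logs:
#' only Stop trials are epoched. Each epoch is the sum over sources of
#' (subject topography) x (baseline ERP + windowed trial amplitude) plus
#' i.i.d. Gaussian sensor noise. Per-subject topographies are seeded
#' jitters of the group topography. Trial amplitudes within a condition
#' are empirically standardized (exact mean 0, SD 1) before the condition
#' shift of \code{+/- effect_size/2} is added, so that with zero noise and
#' zero effect the condition means are exactly equal.
#'
#' @param logs named list of trial logs as from \code{\link{simulate_cohort}}.
#' @param truth a \code{\link{ground_truth}} object; \code{truth$n_subjects}
#'   must equal \code{length(logs)}.
#' @return an object of class \code{epochs_set}: list with \code{epochs}
#'   (per subject, per condition arrays trials x 60 x 307), \code{times},
#'   \code{channels}, \code{subject_topographies} (60 x sources x subjects)
#'   and the generating \code{truth}.
#' @export
generate_group_eeg <- function(logs, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(logs) != truth$n_subjects)
    stop("generate_group_eeg: length(logs) must equal truth$n_subjects")
  times <- epoch_times()
  n_ch <- 60L
  n_t <- length(times)
  n_src <- length(truth$sources)
  channels <- rownames(electrode_layout())
  conds <- c("congruent", "incongruent")
  cond_shift <- c(congruent = -0.5, incongruent = +0.5)

  win_mask <- vapply(truth$sources, function(s)
    as.numeric(times >= s$window_ms[1] & times <= s$window_ms[2]),
    numeric(n_t))                                      # n_t x n_src
  base_erp <- vapply(truth$sources, `[[`, numeric(n_t), "baseline_erp")
  group_topo <- vapply(truth$sources, `[[`, numeric(n_ch), "topography")
  eff <- vapply(truth$sources, `[[`, numeric(1), "effect_size")

  sub_topo <- array(NA_real_, c(n_ch, n_src, length(logs)))
  epochs <- vector("list", length(logs))
  names(epochs) <- names(logs)

  for (s in seq_along(logs)) {
    set.seed(truth$seed + 1000L * s)
    topo_s <- group_topo
    if (truth$subject_jitter > 0) {
      topo_s <- topo_s + matrix(stats::rnorm(n_ch * n_src,
                                             sd = truth$subject_jitter),
                                n_ch, n_src)
      topo_s <- sweep(topo_s, 2, sqrt(colSums(topo_s^2)), "/")
    }
    sub_topo[, , s] <- topo_s
    log <- logs[[s]]
    per_cond <- list()
    for (cc in conds) {
      n_tr <- sum(log$is_stop == 1L & log$condition == cc)
      if (n_tr < 2L)
        stop("generate_group_eeg: need >= 2 Stop trials per condition (",
             names(logs)[s], ", ", cc, ")")
      # trial amplitudes: exact mean 0 / SD 1, plus the condition shift
      amp <- vapply(seq_len(n_src), function(k) {
        a <- as.vector(scale(stats::rnorm(n_tr)))
        a + cond_shift[[cc]] * eff[k]
      }, numeric(n_tr))                                # n_tr x n_src
      # per-trial baseline gains: empirically centered, so condition
      # means stay exactly equal under a null effect
      gain <- if (truth$trial_gain_sd > 0)
        vapply(seq_len(n_src), function(k)
          1 + truth$trial_gain_sd * as.vector(scale(stats::rnorm(n_tr))),
          numeric(n_tr))
      else matrix(1, n_tr, n_src)
      # activations: trials x sources x samples
      arr <- array(0, c(n_tr, n_ch, n_t))
      for (k in seq_len(n_src)) {
        act <- outer(gain[, k], base_erp[, k]) +
          outer(amp[, k], win_mask[, k])               # n_tr x n_t
        arr <- arr + outer(topo_s[, k], act) |> aperm(c(2, 1, 3))
      }
      if (truth$noise_sd > 0)
        arr <- arr + array(stats::rnorm(length(arr), sd = truth$noise_sd),
                           dim(arr))
      dimnames(arr) <- list(NULL, channels, NULL)
      per_cond[[cc]] <- arr
    }
    epochs[[s]] <- per_cond
  }
  structure(list(epochs = epochs, times = times, channels = channels,
                 subject_topographies = sub_topo, truth = truth),
            class = "epochs_set")
}
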