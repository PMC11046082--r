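#' Task design for the combined Simon / Stop-Signal session
#'
#' Describes the trial structure of one session: total trial count, the
#' Go/Stop split, the even congruency split within each trial type, the
#' block structure, and the stop-signal-delay (SSD) staircase settings.
#' Defaults mirror the study design: 936 trials in 9 blocks of 80 Go +
#' 24 Stop trials, congruency balanced within block, staircase starting
#' at 250 ms moving in 50 ms steps within [50, 1000] ms.
#'
#' @param n_blocks number of blocks.
#' @param go_per_block Go trials per block (split evenly between congruent
#'   and incongruent).
#' @param stop_per_block Stop trials per block (split evenly between
#'   congruent and incongruent).
#' @param ssd_initial initial SSD in ms, used independently for each
#'   congruency condition's staircase.
#' @param ssd_step staircase step in ms (+step after a correct rejection,
#'   -step after a failed stop).
#' @param ssd_min,ssd_max staircase bounds in ms.
#' @param go_duration_ms response window on Go trials; a Go trial with no
#'   response within this window is a miss.
#' @param epoch_event event defining time zero of EEG epochs, either the
#'   go-stimulus (letter) onset or the stop-signal onset.
#' @return an object of class \code{task_design} (a list).
#' @export
task_design <- function(n_blocks = 9L,
                        go_per_block = 80L,
                        stop_per_block = 24L,
                        ssd_initial = 250,
                        ssd_step = 50,
                        ssd_min = 50,
                        ssd_max = 1000,
                        go_duration_ms = 1700,
                        epoch_event = c("letter", "stop_signal")) {
  epoch_event <- match.arg(epoch_event)
  if (n_blocks < 1L)
    stop("task_design: n_blocks must be >= 1")
  if (go_per_block %% 2L != 0L || stop_per_block %% 2L != 0L)
    stop("task_design: per-block Go and Stop counts must be even ",
         "(congruent/incongruent split)")
  if (!(ssd_min <= ssd_initial && ssd_initial <= ssd_max))
    stop("task_design: ssd_initial must lie within [ssd_min, ssd_max]")
  if (ssd_step <= 0) stop("task_design: ssd_step must be positive")
  structure(list(
    n_blocks = as.integer(n_blocks),
    go_per_block = as.integer(go_per_block),
    stop_per_block = as.integer(stop_per_block),
    n_trials = as.integer(n_blocks * (go_per_block + stop_per_block)),
    n_go = as.integer(n_blocks * go_per_block),
    n_stop = as.integer(n_blocks * stop_per_block),
    ssd_initial = ssd_initial,
    ssd_step = ssd_step,
    ssd_min = ssd_min,
    ssd_max = ssd_max,
    go_duration_ms = go_duration_ms,
    epoch_event = epoch_event
  ), class = "task_design")
}

#' Staircase update of the stop-signal delay
#'
#' One step of the tracking rule: after a correct rejection the SSD is
#' increased by the step (stopping gets harder), after a failed stop it is
#' decreased, and the result is clamped to the staircase bounds.
#'
#' @param current_ssd current SSD in ms, within \code{[ssd_min, ssd_max]}.
#' @param stopped logical; \code{TRUE} if the response was successfully
#'   withheld on the current Stop trial.
#' @param step step size in ms.
#' @param ssd_min,ssd_max bounds in ms.
#' @return the next SSD in ms.
#' @export
next_ssd <- function(current_ssd, stopped, step = 50,
                     ssd_min = 50, ssd_max = 1000) {
  if (!is.numeric(current_ssd) || length(current_ssd) != 1L ||
      is.na(current_ssd) || current_ssd < ssd_min || current_ssd > ssd_max)
    stop("next_ssd: current_ssd must be a single value in [",
         ssd_min, ", ", ssd_max, "]")
  if (!is.logical(stopped) || length(stopped) != 1L || is.na(stopped))
    stop("next_ssd: stopped must be TRUE or FALSE")
  min(max(current_ssd + if (stopped) step else -step, ssd_min), ssd_max)
}
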