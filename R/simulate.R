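#' Simulate one behavioral session of the Simon / Stop-Signal task
#'
#' Runs the independent race model through a full session: trial order is
#' randomized within blocks (balanced Go/Stop and congruency counts per
#' block), go and stop finishing times are drawn from the ex-Gaussian
#' distributions in \code{race}, and the stop-signal delay follows the
#' tracking staircase separately for congruent and incongruent Stop
#' trials. On a Stop trial a response is emitted iff the go process
#' finishes within the response window and before the stop process, i.e.
#' \code{t_go < ssd + t_stop}.
#'
#' Trials where the mean reaction time over the preceding 50 responded
#' trials exceeds 450 ms are logged in the \code{"speed_warnings"}
#' attribute (trial indices); the warning does not alter simulated RTs.
#'
#' @param race a \code{\link{race_params}} object.
#' @param design a \code{\link{task_design}} object.
#' @param seed integer RNG seed.
#' @return a data.frame with one row per trial and columns \code{block},
#'   \code{trial}, \code{condition}, \code{position}, \code{is_stop},
#'   \code{ssd_ms} (NA on Go trials), \code{rt_ms} (NA when no response),
#'   \code{response} (\code{left}/\code{right}/\code{none}) and
#'   \code{outcome} (\code{hit}, \code{incorrect}, \code{miss},
#'   \code{correct_rejection}, \code{failed_stop}).
#' @export
generate_session <- function(race = race_params(), design = task_design(),
                             seed = 1L) {
  stopifnot(inherits(race, "race_params"), inherits(design, "task_design"))
  set.seed(seed)
  conds <- c("congruent", "incongruent")

  # per-block balanced trial types, shuffled
  block_types <- c(rep("go.congruent", design$go_per_block / 2L),
                   rep("go.incongruent", design$go_per_block / 2L),
                   rep("stop.congruent", design$stop_per_block / 2L),
                   rep("stop.incongruent", design$stop_per_block / 2L))
  per_block <- length(block_types)
  type <- unlist(lapply(seq_len(design$n_blocks),
                        function(b) sample(block_types)))
  n <- length(type)
  is_stop <- startsWith(type, "stop")
  condition <- sub("^(go|stop)\\.", "", type)

  position <- sample(c("left", "right"), n, replace = TRUE)
  # correct effector: stimulus side when congruent, opposite when incongruent
  correct_side <- ifelse(condition == "congruent", position,
                         ifelse(position == "left", "right", "left"))

  t_go <- numeric(n)
  for (cc in conds) {
    idx <- condition == cc
    t_go[idx] <- rexgauss(sum(idx), race$go_mu[[cc]], race$go_sigma[[cc]],
                          race$go_tau[[cc]])
  }
  t_go <- pmax(t_go, 1)                        # RTs are positive
  go_missing <- stats::runif(n) < race$miss_rate | t_go > design$go_duration_ms
  is_error <- stats::runif(n) < race$error_rate

  t_stop <- rep(NA_real_, n)
  for (cc in conds) {
    idx <- is_stop & condition == cc
    t_stop[idx] <- rexgauss(sum(idx), race$ssrt_mu[[cc]],
                            race$ssrt_sigma[[cc]], race$ssrt_tau[[cc]])
  }

  ssd <- rep(NA_real_, n)
  responded <- !go_missing
  # staircase: sequential over Stop trials, tracked per condition
  cur <- c(congruent = design$ssd_initial, incongruent = design$ssd_initial)
  for (i in which(is_stop)) {
    cc <- condition[i]
    ssd[i] <- cur[[cc]]
    responded[i] <- !go_missing[i] && t_go[i] < ssd[i] + t_stop[i]
    cur[[cc]] <- next_ssd(cur[[cc]], stopped = !responded[i],
                          step = design$ssd_step,
                          ssd_min = design$ssd_min, ssd_max = design$ssd_max)
  }

  rt <- ifelse(responded, t_go, NA_real_)
  response <- rep("none", n)
  response[responded] <- ifelse(is_error[responded],
                                ifelse(correct_side[responded] == "left",
                                       "right", "left"),
                                correct_side[responded])
  outcome <- character(n)
  outcome[!is_stop] <- ifelse(!responded[!is_stop], "miss",
                              ifelse(is_error[!is_stop], "incorrect", "hit"))
  outcome[is_stop] <- ifelse(responded[is_stop], "failed_stop",
                             "correct_rejection")

  log <- data.frame(
    block = rep(seq_len(design$n_blocks), each = per_block),
    trial = seq_len(n),
    condition = condition,
    position = position,
    is_stop = as.integer(is_stop),
    ssd_ms = ssd,
    rt_ms = rt,
    response = response,
    outcome = outcome,
    stringsAsFactors = FALSE
  )
  attr(log, "speed_warnings") <- speed_warning_trials(rt)
  attr(log, "seed") <- seed
  log
}

# Trials whose preceding 50 responded trials have mean RT above the cutoff.
speed_warning_trials <- function(rt, window = 50L, cutoff_ms = 450) {
  resp <- which(!is.na(rt))
  if (length(resp) < window) return(integer(0))
  m <- stats::filter(rt[resp], rep(1 / window, window), sides = 1)
  resp[which(!is.na(m) & m > cutoff_ms)]
}

#' Simulate a cohort of sessions
#'
#' @param n_subjects number of subjects.
#' @param race,design as in \code{\link{generate_session}}.
#' @param seed master seed; subject \code{s} uses \code{seed + s - 1}.
#' @return named list of trial logs (\code{sub-01}, \code{sub-02}, ...).
#' @export
simulate_cohort <- function(n_subjects = 53L, race = race_params(),
                            design = task_design(), seed = 1L) {
  logs <- lapply(seq_len(n_subjects), function(s)
    generate_session(race, design, seed = seed + s - 1L))
  names(logs) <- sprintf("sub-%02d", seq_len(n_subjects))
  logs
}
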