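#' Read / write trial logs
#'
#' Trial logs are TSV files with columns \code{subject}, \code{block},
#' \code{trial}, \code{condition}, \code{position}, \code{is_stop},
#' \code{ssd_ms}, \code{rt_ms}, \code{response}, \code{outcome}; empty
#' fields encode missing RT/SSD.
#'
#' @param logs named list of per-subject trial logs.
#' @param path file path.
#' @return \code{read_trial_logs} returns a named list of per-subject
#'   data.frames; \code{write_trial_logs} returns \code{path} invisibly.
#' @export
write_trial_logs <- function(logs, path) {
  all <- do.call(rbind, lapply(names(logs), function(nm)
    cbind(subject = nm, logs[[nm]])))
  utils::write.table(all, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_trial_logs
#' @export
read_trial_logs <- function(path) {
  all <- utils::read.delim(path, sep = "\t", na.strings = "",
                           stringsAsFactors = FALSE)
  validate_trial_log(all)
  split(all[setdiff(names(all), "subject")], all$subject)
}

valid_outcomes <- c("hit", "incorrect", "miss", "correct_rejection",
                    "failed_stop")

validate_trial_log <- function(log) {
  need <- c("condition", "position", "is_stop", "ssd_ms", "rt_ms",
            "response", "outcome")
  miss <- setdiff(need, names(log))
  if (length(miss))
    stop("trial log: missing columns ", paste(miss, collapse = ", "))
  if (!all(log$outcome %in% valid_outcomes))
    stop("trial log: unknown outcome label(s): ",
         paste(setdiff(unique(log$outcome), valid_outcomes), collapse = ", "))
  stop_rows <- log$is_stop == 1L
  if (any(is.na(log$ssd_ms[stop_rows])))
    stop("trial log: Stop trials must carry an SSD")
  if (any(!is.na(log$ssd_ms[!stop_rows])))
    stop("trial log: Go trials must not carry an SSD")
  if (any(!is.na(log$rt_ms) & log$rt_ms <= 0))
    stop("trial log: RTs must be positive when present")
  invisible(log)
}

#' Tally trial outcomes per condition
#'
#' Go outcomes are \code{hit}, \code{incorrect}, \code{miss}; Stop
#' outcomes are \code{correct_rejection}, \code{failed_stop}. The counts
#' partition the trials.
#'
#' @param records a trial log data.frame.
#' @return a condition x outcome integer matrix (all five outcome columns
#'   always present).
#' @export
classify_trials <- function(records) {
  validate_trial_log(records)
  conds <- c("congruent", "incongruent")
  tab <- table(factor(records$condition, levels = conds),
               factor(records$outcome, levels = valid_outcomes))
  m <- matrix(as.integer(tab), nrow = length(conds),
              dimnames = list(conds, valid_outcomes))
  m
}

#' Estimate SSRT by the mean method
#'
#' Mean of the correct Go reaction times minus the mean stop-signal delay
#' over the Stop trials of the condition. Under staircase tracking toward
#' a stopping probability of 0.5 the mean SSD estimates the delay at
#' which responding and stopping are equally likely, making the
#' difference an estimate of the stop-process latency.
#'
#' @param records a trial log data.frame.
#' @param condition \code{"congruent"} or \code{"incongruent"}.
#' @return SSRT estimate in ms.
#' @export
estimate_ssrt <- function(records, condition = c("congruent", "incongruent")) {
  condition <- match.arg(condition)
  validate_trial_log(records)
  sel <- records$condition == condition
  go_rt <- records$rt_ms[sel & records$is_stop == 0L &
                           records$outcome == "hit"]
  ssd <- records$ssd_ms[sel & records$is_stop == 1L]
  if (length(go_rt) < 1L)
    stop("estimate_ssrt: no correct Go trials in condition '", condition, "'")
  if (length(ssd) < 1L)
    stop("estimate_ssrt: no Stop trials in condition '", condition, "'")
  mean(go_rt) - mean(ssd)
}

#' Per-subject, per-condition behavioral summary
#'
#' @param logs named list of per-subject trial logs.
#' @return a data.frame with one row per subject x condition and columns
#'   \code{mean_go_rt}, \code{go_accuracy}, \code{p_respond_stop},
#'   \code{mean_ssd}, \code{ssrt} (= \code{mean_go_rt - mean_ssd}) and
#'   \code{mean_failed_stop_rt}.
#' @export
summarize_behavior <- function(logs) {
  rows <- list()
  for (nm in names(logs)) {
    log <- logs[[nm]]
    validate_trial_log(log)
    for (cc in c("congruent", "incongruent")) {
      sel <- log$condition == cc
      go <- log[sel & log$is_stop == 0L, ]
      st <- log[sel & log$is_stop == 1L, ]
      fs_rt <- st$rt_ms[st$outcome == "failed_stop"]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = nm, condition = cc,
        mean_go_rt = mean(go$rt_ms[go$outcome == "hit"]),
        go_accuracy = mean(go$outcome == "hit"),
        p_respond_stop = mean(st$outcome == "failed_stop"),
        mean_ssd = mean(st$ssd_ms),
        ssrt = estimate_ssrt(log, cc),
        mean_failed_stop_rt = if (length(fs_rt)) mean(fs_rt) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Apply cohort exclusion rules
#'
#' Three rules, mirroring standard stop-signal quality criteria:
#' \itemize{
#'   \item \code{stop_probability}: stopping probability outside the
#'     reliable tracking range, i.e. p(respond|stop) outside
#'     \code{[0.25, 0.75]} in either condition;
#'   \item \code{ssrt_direction}: SSRT difference (incongruent minus
#'     congruent) larger than +50 ms, i.e. not in the expected direction
#'     within tolerance;
#'   \item \code{tukey_outlier}: Tukey-fence outlier
#'     (outside \code{[Q1 - 1.5 IQR, Q3 + 1.5 IQR]}, quartiles of type 6
#'     as in SPSS) in more than one of the eight measurements
#'     \{mean Go RT, Go accuracy, SSRT, p(respond|stop)\} x condition.
#' }
#'
#' @param summaries output of \code{\link{summarize_behavior}}.
#' @param p_range allowed stopping-probability range.
#' @param ssrt_cutoff_ms cutoff on the incongruent-minus-congruent SSRT
#'   difference.
#' @return an \code{exclusion_report} data.frame: one row per subject with
#'   \code{included} flag and comma-separated \code{reasons}.
#' @export
apply_exclusions <- function(summaries, p_range = c(0.25, 0.75),
                             ssrt_cutoff_ms = 50) {
  subjects <- unique(summaries$subject)
  reasons <- stats::setNames(vector("list", length(subjects)), subjects)

  for (nm in subjects) {
    s <- summaries[summaries$subject == nm, ]
    if (any(s$p_respond_stop < p_range[1] | s$p_respond_stop > p_range[2]))
      reasons[[nm]] <- c(reasons[[nm]], "stop_probability")
    d <- s$ssrt[s$condition == "incongruent"] - s$ssrt[s$condition == "congruent"]
    if (d > ssrt_cutoff_ms)
      reasons[[nm]] <- c(reasons[[nm]], "ssrt_direction")
  }

  measures <- c("mean_go_rt", "go_accuracy", "ssrt", "p_respond_stop")
  if (length(subjects) >= 4L) {
    n_flags <- stats::setNames(integer(length(subjects)), subjects)
    for (cc in c("congruent", "incongruent")) {
      s <- summaries[summaries$condition == cc, ]
      for (m in measures) {
        x <- s[[m]]
        q <- stats::quantile(x, c(0.25, 0.75), type = 6, names = FALSE)
        lo <- q[1] - 1.5 * (q[2] - q[1])
        hi <- q[2] + 1.5 * (q[2] - q[1])
        out <- s$subject[x < lo | x > hi]
        n_flags[out] <- n_flags[out] + 1L
      }
    }
    for (nm in subjects[n_flags[subjects] > 1L])
      reasons[[nm]] <- c(reasons[[nm]], "tukey_outlier")
  } else {
    warning("apply_exclusions: fewer than 4 subjects; Tukey rule skipped")
  }

  data.frame(
    subject = subjects,
    included = vapply(reasons, function(r) length(r) == 0L, logical(1)),
    reasons = vapply(reasons, paste, character(1), collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired congruency contrast (Wilcoxon signed-rank)
#'
#' Two-sided paired signed-rank test on per-subject values from the two
#' conditions: exact for n <= 25 (requires no ties/zero differences),
#' normal approximation with continuity correction otherwise.
#'
#' @param congruent,incongruent paired per-subject values (same subjects,
#'   same order).
#' @return list with \code{statistic} (V), \code{p}, \code{n} and
#'   \code{method}.
#' @export
congruency_contrast <- function(congruent, incongruent) {
  if (length(congruent) != length(incongruent))
    stop("congruency_contrast: inputs must be paired")
  d <- incongruent - congruent
  if (all(d == 0)) {
    warning("congruency_contrast: all differences are zero (degenerate input)")
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate"))
  }
  n <- sum(d != 0)
  exact <- n <= 25 && !any(duplicated(abs(d[d != 0])))
  wt <- stats::wilcox.test(incongruent, congruent, paired = TRUE,
                           exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value, n = n,
       method = if (exact) "exact" else "normal approximation")
}
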