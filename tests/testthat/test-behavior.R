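test_that("trial outcomes are tallied per condition and partition the log", {
  counts <- classify_trials(toy_log())
  expect_equal(counts["congruent", "hit"], 1L)
  expect_equal(counts["incongruent", "miss"], 1L)
  expect_equal(counts["congruent", "correct_rejection"], 1L)
  expect_equal(counts["incongruent", "failed_stop"], 1L)
  expect_equal(sum(counts), 4L)

  empty <- toy_log()[0, ]
  expect_true(all(classify_trials(empty) == 0L))

  bad <- toy_log()
  bad$outcome[1] <- "spurious"
  expect_error(classify_trials(bad), "unknown outcome")

  log <- generate_session(seed = 13L)
  counts <- classify_trials(log)
  expect_equal(sum(counts[, c("hit", "incorrect", "miss")]), 720L)
  expect_equal(sum(counts[, c("correct_rejection", "failed_stop")]), 216L)
})

test_that("SSRT by the mean method is mean correct-go RT minus mean SSD", {
  log <- data.frame(
    block = 1L, trial = 1:6,
    condition = "congruent", position = "left",
    is_stop = c(0L, 0L, 0L, 0L, 1L, 1L),
    ssd_ms = c(NA, NA, NA, NA, 230, 230),
    rt_ms = c(500, 500, 510, NA, NA, NA),
    response = c("left", "left", "right", "none", "none", "none"),
    outcome = c("hit", "hit", "incorrect", "miss", "correct_rejection",
                "correct_rejection"),
    stringsAsFactors = FALSE)
  # only the two correct-go RTs (500, 500) enter the go mean
  expect_equal(estimate_ssrt(log, "congruent"), 270)
  log$ssd_ms[5:6] <- 500
  expect_equal(estimate_ssrt(log, "congruent"), 0)
  expect_error(estimate_ssrt(log, "incongruent"), "no correct Go trials")
})

test_that("exclusion rules flag stopping probability, SSRT direction and Tukey outliers", {
  set.seed(42)
  n <- 12L
  mk <- function(subject, cond, go_rt, acc, p_stop, ssd, ssrt)
    data.frame(subject = subject, condition = cond, mean_go_rt = go_rt,
               go_accuracy = acc, p_respond_stop = p_stop, mean_ssd = ssd,
               ssrt = ssrt, mean_failed_stop_rt = go_rt - 60,
               stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    nm <- sprintf("sub-%02d", i)
    rows[[2 * i - 1]] <- mk(nm, "congruent", 494 + rnorm(1, sd = 4), 0.96,
                            0.5 + rnorm(1, sd = 0.02), 224, 270 + rnorm(1, sd = 3))
    rows[[2 * i]] <- mk(nm, "incongruent", 522 + rnorm(1, sd = 4), 0.94,
                        0.5 + rnorm(1, sd = 0.02), 243, 279 + rnorm(1, sd = 3))
  }
  summ <- do.call(rbind, rows)

  # low stopping probability
  summ$p_respond_stop[summ$subject == "sub-01" &
                        summ$condition == "congruent"] <- 0.20
  # SSRT difference (incongruent - congruent) above +50 ms
  summ$ssrt[summ$subject == "sub-02" & summ$condition == "incongruent"] <-
    summ$ssrt[summ$subject == "sub-02" & summ$condition == "congruent"] + 60
  # Tukey outlier in two measurements (go RT and SSRT, congruent)
  idx <- summ$subject == "sub-03" & summ$condition == "congruent"
  summ$mean_go_rt[idx] <- 800
  summ$ssrt[idx] <- 420

  rep <- apply_exclusions(summ)
  reason <- function(nm) rep$reasons[rep$subject == nm]
  expect_false(rep$included[rep$subject == "sub-01"])
  expect_match(reason("sub-01"), "stop_probability")
  expect_match(reason("sub-02"), "ssrt_direction")
  expect_match(reason("sub-03"), "tukey_outlier")
  expect_true(all(rep$included[!rep$subject %in%
                                 c("sub-01", "sub-02", "sub-03")]))
  # excluded iff reasons nonempty
  expect_equal(rep$included, rep$reasons == "")

  # idempotence of the cohort-independent rules on the filtered cohort
  kept <- summ[summ$subject %in% rep$subject[rep$included], ]
  rep2 <- apply_exclusions(kept)
  expect_false(any(grepl("stop_probability|ssrt_direction", rep2$reasons)))

  expect_warning(apply_exclusions(summ[summ$subject %in%
                                         c("sub-01", "sub-02"), ]),
                 "fewer than 4")
})

test_that("congruency contrast is an exact signed-rank test for small n", {
  # n = 6, all differences positive: p = 2/2^6
  res <- congruency_contrast(congruent = rep(0, 6),
                             incongruent = c(1, 2, 3, 4, 5, 6))
  expect_equal(res$p, 2 / 64)
  expect_equal(res$method, "exact")
  expect_warning(res0 <- congruency_contrast(1:5, 1:5), "degenerate")
  expect_equal(res0$p, 1)
  expect_error(congruency_contrast(1:3, 1:4), "paired")
  # large n falls back to the corrected normal approximation
  set.seed(1)
  a <- rnorm(40)
  res2 <- congruency_contrast(a, a + rnorm(40, 0.1))
  expect_equal(res2$method, "normal approximation")
  expect_true(res2$p > 0 && res2$p < 1)
})

test_that("trial logs round-trip through the TSV dialect", {
  logs <- simulate_cohort(2L, design = task_design(n_blocks = 1L), seed = 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_logs(logs, path)
  back <- read_trial_logs(path)
  expect_equal(names(back), names(logs))
  for (nm in names(logs))
    expect_equal(back[[nm]], logs[[nm]], ignore_attr = TRUE)
})
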