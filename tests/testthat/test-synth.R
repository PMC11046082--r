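test_that("generated sessions conserve trial counts overall and per block", {
  log <- generate_session(seed = 7L)
  expect_equal(nrow(log), 936L)
  expect_equal(sum(log$is_stop), 216L)
  expect_equal(sum(log$is_stop == 0L & log$condition == "congruent"), 360L)
  expect_equal(sum(log$is_stop == 1L & log$condition == "congruent"), 108L)
  per_block <- table(log$block, log$is_stop)
  expect_true(all(per_block[, "1"] == 24L))
  expect_true(all(per_block[, "0"] == 80L))
  cong_stop <- table(log$block[log$is_stop == 1L],
                     log$condition[log$is_stop == 1L])
  expect_true(all(cong_stop == 12L))
})

test_that("stop-trial SSDs follow the staircase given the outcomes", {
  log <- generate_session(seed = 9L)
  for (cc in c("congruent", "incongruent")) {
    st <- log[log$is_stop == 1L & log$condition == cc, ]
    expect_equal(st$ssd_ms[1], 250)
    stopped <- st$outcome == "correct_rejection"
    for (i in seq_len(nrow(st) - 1L))
      expect_equal(st$ssd_ms[i + 1L], next_ssd(st$ssd_ms[i], stopped[i]))
  }
})

test_that("a degenerate always-winning stop process yields only correct rejections", {
  rp <- race_params(ssrt_mu = -1e9, ssrt_sigma = 0, ssrt_tau = 0)
  log <- generate_session(rp, seed = 3L)
  st <- log[log$is_stop == 1L, ]
  expect_true(all(st$outcome == "correct_rejection"))
  for (cc in c("congruent", "incongruent")) {
    ssd <- st$ssd_ms[st$condition == cc]
    expect_true(all(diff(ssd) >= 0))
    expect_equal(ssd[length(ssd)], 1000)
  }
})

test_that("race-model signature holds: failed-stop RTs are faster than go RTs", {
  for (s in 1:5) {
    log <- generate_session(seed = s)
    fs <- log$rt_ms[log$outcome == "failed_stop"]
    go <- log$rt_ms[log$outcome == "hit"]
    expect_lt(mean(fs), mean(go))
  }
})

test_that("identical seeds reproduce sessions and epochs bit-for-bit", {
  expect_identical(generate_session(seed = 5L), generate_session(seed = 5L))
  logs <- simulate_cohort(2L, design = task_design(n_blocks = 1L), seed = 4L)
  gt <- ground_truth(n_subjects = 2L, seed = 6L)
  expect_identical(generate_group_eeg(logs, gt), generate_group_eeg(logs, gt))
})

test_that("null construction gives exactly equal condition means in the window", {
  logs <- simulate_cohort(2L, design = task_design(n_blocks = 1L), seed = 8L)
  src <- list(source_spec(smooth_topography(c(0, 0.3)), c(100, 400),
                          effect_size = 0, baseline_erp = rep(0, 307)))
  gt <- ground_truth(sources = src, n_subjects = 2L, noise_sd = 0,
                     trial_gain_sd = 0, seed = 2L)
  eps <- generate_group_eeg(logs, gt)
  x <- eps$epochs[["sub-01"]]
  m_c <- apply(x$congruent, c(2, 3), mean)
  m_i <- apply(x$incongruent, c(2, 3), mean)
  expect_equal(m_c, m_i, tolerance = 1e-12)
})

test_that("a single noiseless source produces rank-1 epochs", {
  eps <- rank1_effect_epochs()
  x <- eps$epochs[["sub-01"]]$congruent
  for (tr in c(1L, 5L)) {
    sv <- svd(x[tr, , ])$d
    expect_lt(sv[2] / sv[1], 1e-10)
  }
})

test_that("pointwise AUC inside the window matches the Gaussian oracle", {
  # effect d shifts trial amplitudes (SD 1): ideal AUC = pnorm(d / sqrt(2))
  eps <- rank1_effect_epochs(n_subjects = 6L)
  a0 <- eps$truth$sources[[1]]$topography
  win <- window_samples()
  aucs <- vapply(eps$epochs, function(x) {
    t <- win[5]
    dec <- c(x$congruent[, , t] %*% a0, x$incongruent[, , t] %*% a0)
    pos <- rep(c(FALSE, TRUE), c(nrow(x$congruent), nrow(x$incongruent)))
    r <- rank(dec)
    n1 <- sum(pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * sum(!pos))
  }, numeric(1))
  expect_equal(mean(aucs), pnorm(1 / sqrt(2)), tolerance = 0.05)
})

test_that("epoch geometry matches the 256 Hz half-open grid", {
  tt <- epoch_times()
  expect_length(tt, 307L)
  expect_equal(tt[1], -200)
  expect_equal(diff(tt)[1], 1000 / 256)
  expect_lt(tt[307], 1000)
  eps <- small_study()$epochs
  expect_equal(dim(eps$epochs[[1]]$congruent)[2:3], c(60L, 307L))
  # only Stop trials are epoched
  log <- small_study()$logs[[1]]
  expect_equal(dim(eps$epochs[[1]]$congruent)[1],
               sum(log$is_stop == 1L & log$condition == "congruent"))
})

test_that("speed warnings are logged without altering the trial data", {
  rp <- race_params(go_mu = c(congruent = 600, incongruent = 620))
  log <- generate_session(rp, seed = 2L)
  expect_gt(length(attr(log, "speed_warnings")), 0L)
  expect_equal(nrow(log), 936L)
})
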