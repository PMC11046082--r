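# Small synthetic tensors: n trials per class, 60 channels, nt samples.
mk_tensors <- function(n = 20L, nt = 12L, seed = 1L,
                       signal_at = integer(0), d = 2,
                       reversed_at = integer(0)) {
  set.seed(seed)
  a <- rnorm(60)
  a <- a / sqrt(sum(a^2))
  mk <- function(shift) {
    arr <- array(rnorm(n * 60 * nt, sd = 1), c(n, 60L, nt))
    for (t in signal_at)
      arr[, , t] <- arr[, , t] + outer(rnorm(n, shift), a)
    for (t in reversed_at)
      arr[, , t] <- arr[, , t] + outer(rnorm(n, -shift), a)
    arr
  }
  list(cong = mk(-d / 2), incong = mk(d / 2))
}

test_that("uninformative labels decode at chance", {
  tn <- mk_tensors(n = 40L, nt = 20L, seed = 2L)   # no signal anywhere
  d <- decode_timecourse(tn$cong, tn$incong, seed = 3L)
  expect_equal(mean(d$auc_diag), 0.5, tolerance = 0.06)
  expect_true(all(d$auc_diag >= 0 & d$auc_diag <= 1))
})

test_that("a perfectly separated sample decodes perfectly, others at chance", {
  tn <- mk_tensors(n = 20L, seed = 4L, signal_at = 5L, d = 50)
  d <- decode_timecourse(tn$cong, tn$incong, seed = 1L)
  expect_equal(d$auc_diag[5], 1)
  expect_equal(mean(d$auc_diag[-5]), 0.5, tolerance = 0.07)
})

test_that("the d = 1 Gaussian shift decodes at the closed-form AUC", {
  eps <- rank1_effect_epochs(n_subjects = 8L)
  win <- window_samples()
  aucs <- vapply(eps$epochs, function(x)
    mean(decode_timecourse(x$congruent, x$incongruent,
                           seed = 7L)$auc_diag[win]), numeric(1))
  expect_equal(mean(aucs), pnorm(1 / sqrt(2)), tolerance = 0.05)
})

test_that("under-sampling balances classes within every fold", {
  tn <- mk_tensors(n = 23L, seed = 5L)
  d <- decode_timecourse(tn$cong[1:23, , ], tn$incong[1:17, , ], seed = 2L)
  expect_equal(unname(d$n_trials_used), c(17L, 17L))
  fb <- d$folds
  expect_equal(length(fb$keep_congruent), 17L)
  for (f in 1:5) {
    expect_equal(sum(fb$fold_congruent == f), sum(fb$fold_incongruent == f))
  }
  expect_error(decode_timecourse(tn$cong[1:4, , ], tn$incong, seed = 2L),
               "reduce n_folds")
})

test_that("decoding is deterministic given the seed", {
  tn <- mk_tensors(n = 12L, nt = 6L, seed = 6L)
  d1 <- decode_timecourse(tn$cong, tn$incong, seed = 9L)
  d2 <- decode_timecourse(tn$cong, tn$incong, seed = 9L)
  expect_identical(d1$auc_diag, d2$auc_diag)
})

test_that("temporal generalization reuses patterns and reflects reversed ones", {
  # average the AUC matrix over replicate constructions: single-run fold
  # AUCs carry ~0.06 SD at this size
  tgs <- lapply(1:5, function(s) {
    tn <- mk_tensors(n = 30L, nt = 8L, seed = s, signal_at = c(2L, 5L),
                     reversed_at = 7L, d = 3)
    temporal_generalization(tn$cong, tn$incong, seed = 4L)
  })
  M <- Reduce(`+`, lapply(tgs, `[[`, "auc_tg")) / 5
  # identical pattern at 2 and 5: cross-generalization matches diagonal
  expect_lt(abs(M[2, 5] - M[2, 2]), 0.08)
  # reversed pattern at 7: decoding reflects about chance
  expect_lt(abs(M[2, 7] - (1 - M[2, 2])), 0.08)
  # no information off the signal samples
  expect_lt(abs(mean(M[2, c(1, 3, 4, 6, 8)]) - 0.5), 0.08)
  # the diagonal analysis with the same seed is the matrix diagonal
  tn <- mk_tensors(n = 30L, nt = 8L, seed = 1L, signal_at = c(2L, 5L),
                   reversed_at = 7L, d = 3)
  tg <- temporal_generalization(tn$cong, tn$incong, seed = 4L)
  expect_equal(tg$auc_diag, diag(tg$auc_tg))
  d <- decode_timecourse(tn$cong, tn$incong, seed = 4L)
  expect_identical(d$auc_diag, tg$auc_diag)
})

test_that("back-projected pairs are rank-1 with channel norms equal to |activation|", {
  st <- small_study()
  bp <- backproject_pair(st$pairs[1, ], st$gica$congruent,
                         st$gica$incongruent, st$epochs, "sub-01")
  x <- bp$congruent
  sv <- svd(x[2, , ])$d
  expect_lt(sv[2] / sv[1], 1e-10)
  # unit-norm topography: channel-profile norm recovers |activation|
  nrm <- sqrt(colSums(x[2, , ]^2))
  expect_equal(nrm, abs(bp$activation_congruent[2, ]), tolerance = 1e-10)
  expect_error(backproject_pair(st$pairs[1, ], st$gica$congruent,
                                st$gica$incongruent, st$epochs, "sub-99"),
               "unknown subject")
})

test_that("decision-value AUC agrees with the reference SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(11)
  n <- 80L
  X <- matrix(rnorm(2 * n * 20), 2 * n, 20)
  X[(n + 1):(2 * n), 1:5] <- X[(n + 1):(2 * n), 1:5] + 0.4
  y <- rep(c(-1, 1), each = n)
  tr <- c(1:60, (n + 1):(n + 60))
  te <- setdiff(seq_len(2 * n), tr)
  w <- conflictstop:::linsvm_fit(X[tr, ], y[tr], tol = 1e-5,
                                 max_epochs = 20000L)
  dec_mine <- X[te, ] %*% w[1:20] + w[21]
  m <- e1071::svm(X[tr, ], factor(y[tr]), kernel = "linear", cost = 1,
                  scale = FALSE)
  dec_ref <- attr(predict(m, X[te, ], decision.values = TRUE),
                  "decision.values")
  flip <- if (stats::cor(as.vector(dec_ref), dec_mine) < 0) -1 else 1
  auc <- function(dec) {
    r <- rank(dec)
    pos <- y[te] == 1
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }
  expect_gt(abs(stats::cor(as.vector(dec_ref), dec_mine)), 0.995)
  expect_equal(auc(flip * as.vector(dec_ref)), auc(dec_mine),
               tolerance = 0.02)
})
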