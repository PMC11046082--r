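channels60 <- sprintf("E%02d", 1:60)

toy_epochs <- function(n_trials, n_samples = 307L, seed = 1L) {
  set.seed(seed)
  arr <- array(rnorm(n_trials * 60 * n_samples), c(n_trials, 60L, n_samples))
  dimnames(arr) <- list(NULL, channels60, NULL)
  arr
}

test_that("concatenation orders columns by subject/trial/sample and centers channels", {
  arrs <- list(`sub-01` = toy_epochs(3L), `sub-02` = toy_epochs(3L, seed = 2L))
  conc <- concatenate_epochs(arrs)
  expect_equal(ncol(conc$X), 2L * 3L * 307L)
  expect_equal(max(abs(rowMeans(conc$X))), 0, tolerance = 1e-12)
  # first block of columns is subject 1, trial 1, samples in order
  expect_equal(conc$X[, 1:307] + conc$center,
               arrs[["sub-01"]][1, , ], ignore_attr = TRUE)
  expect_equal(conc$X[, 308:614] + conc$center,
               arrs[["sub-01"]][2, , ], ignore_attr = TRUE)

  one <- concatenate_epochs(arrs[1])
  expect_equal(ncol(one$X), 3L * 307L)

  # ragged trial counts: column count is the sum over subjects
  ragged <- list(a = toy_epochs(2L), b = toy_epochs(5L, seed = 3L),
                 c = toy_epochs(1L, seed = 4L))
  expect_equal(ncol(concatenate_epochs(ragged)$X), (2L + 5L + 1L) * 307L)

  bad <- arrs
  dimnames(bad[[2]])[[2]] <- rev(channels60)
  expect_error(concatenate_epochs(bad), "mismatched channel")
})

test_that("PCA retention rule picks the smallest sufficient dimension", {
  set.seed(3)
  # exact rank-3 data
  A <- matrix(rnorm(60 * 3), 60, 3)
  X <- A %*% matrix(rnorm(3 * 4000), 3)
  X <- X - rowMeans(X)
  red <- pca_reduce(X, retention = 0.98)
  expect_equal(red$n_retained, 3L)
  # whitened scores have identity covariance
  expect_equal(tcrossprod(red$scores) / (ncol(X) - 1), diag(3),
               tolerance = 1e-8)
  # isotropic noise: flat spectrum hits the k_max cap
  N <- matrix(rnorm(60 * 8000), 60)
  N <- N - rowMeans(N)
  expect_equal(pca_reduce(N, retention = 0.98, k_max = 20L)$n_retained, 20L)
  # full retention of full-rank data keeps all 60 channels
  expect_equal(pca_reduce(N, retention = 1, k_max = 60L)$n_retained, 60L)
  expect_error(pca_reduce(N, retention = 1.2), "retention")
})

test_that("fixed-point ICA recovers a known Laplacian mixture", {
  set.seed(4)
  S <- matrix(stats::rexp(2 * 20000) * sample(c(-1, 1), 40000, TRUE), 2)
  A <- matrix(rnorm(120), 60, 2)
  X <- A %*% S
  conc <- list(X = X - rowMeans(X), center = rowMeans(X),
               channels = channels60, blocks = NULL)
  g <- fit_group_ica(conc, seed = 3L)
  expect_equal(g$n_retained, 2L)
  cr <- abs(stats::cor(A, g$A))
  expect_gt(best_assignment(cr)$total / 2, 0.99)
  # unit-norm topographies with positive max-|entry|
  expect_equal(colSums(g$A^2), rep(1, 2), tolerance = 1e-10)
  for (j in 1:2) expect_gt(g$A[which.max(abs(g$A[, j])), j], 0)
  # W A = identity on the retained subspace
  expect_equal(g$W %*% g$A, diag(2), tolerance = 1e-8)
  # determinism
  g2 <- fit_group_ica(conc, seed = 3L)
  expect_identical(g$W, g2$W)
})

test_that("back-reconstruction is the exact demixing projection", {
  st <- small_study()
  g <- st$gica$congruent
  arr <- st$epochs$epochs[[2]]$congruent
  Cs <- back_reconstruct(g, arr)
  expect_equal(dim(Cs), c(dim(arr)[1], g$n_retained, 307L))
  # C_s = W X_s exactly, for a spot-checked trial/sample
  x <- arr[3, , 10] - g$center
  expect_equal(Cs[3, , 10], as.vector(g$W %*% x))
  # zero input maps to zero activations (centering aside)
  zero <- array(rep(g$center, each = 2), c(2L, 60L, 307L)) * 0 +
    aperm(array(g$center, c(60L, 307L, 2L)), c(3, 1, 2))
  expect_equal(max(abs(back_reconstruct(g, zero))), 0, tolerance = 1e-9)
  expect_error(back_reconstruct(g, arr[, 1:10, , drop = FALSE]),
               "channel count")
})

test_that("group decomposition reconstructs the retained-subspace projection", {
  st <- small_study()
  g <- st$gica$congruent
  arr <- st$epochs$epochs[[1]]$congruent
  Xc <- arr[1, , ] - g$center                   # 60 x 307
  Cs <- g$W %*% Xc
  proj <- g$A %*% Cs
  # A C equals the projection of X onto the span of A
  P <- g$A %*% solve(crossprod(g$A)) %*% t(g$A)
  expect_equal(proj, P %*% Xc, tolerance = 1e-8)
})

test_that("condition decompositions are fitted independently", {
  st <- small_study()
  expect_false(identical(st$gica$congruent$W, st$gica$incongruent$W))
  # both still recover the same ground-truth topographies
  truth <- vapply(st$truth$sources, `[[`, numeric(60), "topography")
  for (cc in c("congruent", "incongruent")) {
    rec <- best_assignment(abs(stats::cor(truth, st$gica[[cc]]$A)))$total / 4
    expect_gt(rec, 0.9)
  }
})
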