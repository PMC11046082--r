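#' Concatenate Stop-trial epochs across subjects
#'
#' Builds the aggregate channels x time data matrix for one condition:
#' column blocks ordered by (subject, trial, sample), per-channel grand
#' mean removed. All subjects must share the channel order and time axis.
#'
#' @param epochs an \code{epochs_set} (see \code{\link{generate_group_eeg}})
#'   or a named list of per-subject arrays (trials x channels x samples).
#' @param condition \code{"congruent"} or \code{"incongruent"}; ignored
#'   when a plain list of arrays is supplied.
#' @return list with \code{X} (60 x N centered matrix), \code{center}
#'   (per-channel means), \code{blocks} (data.frame subject / n_trials /
#'   n_samples) and \code{channels}.
#' @export
concatenate_epochs <- function(epochs, condition = c("congruent",
                                                     "incongruent")) {
  if (inherits(epochs, "epochs_set")) {
    condition <- match.arg(condition)
    arrs <- lapply(epochs$epochs, `[[`, condition)
    channels <- epochs$channels
  } else {
    arrs <- epochs
    channels <- dimnames(arrs[[1]])[[2]]
  }
  n_ch <- dim(arrs[[1]])[2]
  for (a in arrs) {
    if (dim(a)[2] != n_ch ||
        !identical(dimnames(a)[[2]], dimnames(arrs[[1]])[[2]]))
      stop("concatenate_epochs: subjects have mismatched channel sets")
  }
  mats <- lapply(arrs, epochs_to_matrix)
  X <- do.call(cbind, mats)
  center <- rowMeans(X)
  X <- X - center
  blocks <- data.frame(
    subject = if (is.null(names(arrs))) seq_along(arrs) else names(arrs),
    n_trials = vapply(arrs, function(a) dim(a)[1], integer(1)),
    n_samples = vapply(arrs, function(a) dim(a)[3], integer(1)),
    row.names = NULL)
  list(X = X, center = center, blocks = blocks, channels = channels)
}

# trials x channels x samples -> channels x (trials * samples),
# columns ordered trial-major (trial 1 samples 1..T, trial 2, ...).
epochs_to_matrix <- function(arr) {
  m <- aperm(arr, c(2, 3, 1))                 # ch x samples x trials
  dim(m) <- c(dim(arr)[2], dim(arr)[3] * dim(arr)[1])
  m
}

#' PCA reduction with eigenvalue-retention rule
#'
#' Eigendecomposition of the channel covariance of the centered aggregate
#' matrix; the retained dimension is the smallest k whose cumulative
#' eigenvalue fraction reaches \code{retention}, capped at \code{k_max}.
#' Returns whitened principal-component scores.
#'
#' @param X centered channels x N matrix (or the list returned by
#'   \code{\link{concatenate_epochs}}).
#' @param retention cumulative eigenvalue fraction to retain, in (0, 1].
#' @param k_max cap on the retained dimension.
#' @return list with \code{scores} (k x N, whitened), \code{eigenvalues},
#'   \code{n_retained}, \code{whitening} (k x channels) and
#'   \code{dewhitening} (channels x k).
#' @export
pca_reduce <- function(X, retention = 0.98, k_max = 20L) {
  if (is.list(X)) X <- X$X
  if (!(retention > 0 && retention <= 1))
    stop("pca_reduce: retention must lie in (0, 1]")
  N <- ncol(X)
  cv <- tcrossprod(X) / (N - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  frac <- cumsum(ev) / sum(ev)
  k <- min(which(frac >= retention - 1e-12))
  k <- min(k, k_max)
  if (ev[k] <= 0)
    stop("pca_reduce: retained dimension hits a zero eigenvalue")
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  d <- sqrt(ev[seq_len(k)])
  whitening <- t(U) / d                       # rows scaled by 1/sqrt(ev)
  scores <- whitening %*% X
  list(scores = scores, eigenvalues = ev, n_retained = k,
       whitening = whitening, dewhitening = U * rep(d, each = nrow(U)))
}

# Fixed-point ICA with tanh contrast and symmetric decorrelation on
# whitened data Z (k x N). Returns the orthogonal unmixing matrix (k x k).
# Retained dimensions spanned by near-Gaussian noise have no stable fixed
# point, so on real-scale data the rotation within the noise subspace can
# keep wandering; like the reference fixed-point implementations we return
# the final iterate with a warning in that case (on_nonconvergence =
# "error" restores a hard failure naming the seed).
fastica_core <- function(Z, seed = 1L, tol = 1e-4, max_iter = 200L,
                         alpha = 1,
                         on_nonconvergence = c("warn", "error")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  k <- nrow(Z)
  N <- ncol(Z)
  set.seed(seed)
  W <- sym_decorrelate(matrix(stats::rnorm(k * k), k, k))
  delta <- Inf
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(alpha * WZ)
    W1 <- tcrossprod(G, Z) / N -
      diag(alpha * rowMeans(1 - G^2), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) return(list(W = W, iterations = it, converged = TRUE))
  }
  msg <- paste0("fastica_core: tolerance ", tol, " not reached after ",
                max_iter, " iterations (seed ", seed, ", final delta ",
                signif(delta, 3), ")")
  if (on_nonconvergence == "error") stop(msg)
  warning(msg)
  list(W = W, iterations = max_iter, converged = FALSE)
}

sym_decorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' Fit the group independent-component decomposition
#'
#' Fixed-point ICA (tanh contrast, symmetric decorrelation) on the
#' whitened PCA scores of the aggregate data. The channel-space demixing
#' matrix W composes the ICA rotation with the PCA whitening, so that
#' component activations are \code{C = W X} for raw (centered) channel
#' data X. Topographies A (the pseudo-inverse of W) are normalized to
#' unit Euclidean norm with a positive maximum-magnitude entry; the
#' activations absorb scale and sign.
#'
#' @param conc output of \code{\link{concatenate_epochs}}.
#' @param retention,k_max see \code{\link{pca_reduce}}.
#' @param seed seed for the ICA initialization.
#' @param tol,max_iter fixed-point convergence controls.
#' @return a \code{group_decomposition}: list with \code{W} (components x
#'   channels), \code{A} (channels x components), \code{eigenvalues},
#'   \code{n_retained}, \code{center}, \code{blocks}, \code{channels},
#'   \code{seed}.
#' @export
fit_group_ica <- function(conc, retention = 0.98, k_max = 20L, seed = 1L,
                          tol = 1e-4, max_iter = 200L,
                          on_nonconvergence = "warn") {
  red <- pca_reduce(conc$X, retention = retention, k_max = k_max)
  fit <- fastica_core(red$scores, seed = seed, tol = tol,
                      max_iter = max_iter,
                      on_nonconvergence = on_nonconvergence)
  W <- fit$W %*% red$whitening               # k x channels
  A <- red$dewhitening %*% t(fit$W)          # channels x k (pseudo-inverse)
  # unit-norm topographies with positive max-|entry|; W rescaled to keep
  # the A %*% W back-projection unchanged
  nrm <- sqrt(colSums(A^2))
  sgn <- vapply(seq_len(ncol(A)), function(j) {
    v <- A[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  A <- sweep(A, 2, nrm * sgn, "/")
  W <- sweep(W, 1, nrm * sgn, "*")
  structure(list(W = W, A = A, eigenvalues = red$eigenvalues,
                 n_retained = red$n_retained, center = conc$center,
                 blocks = conc$blocks, channels = conc$channels,
                 seed = seed, iterations = fit$iterations),
            class = "group_decomposition")
}

#' Back-reconstruct per-subject component activations
#'
#' Direct projection \code{C_s = W X_s} of one subject's (centered)
#' epochs onto the group demixing matrix, reshaped to trials x components
#' x samples.
#'
#' @param decomposition a \code{group_decomposition}.
#' @param subject_epochs array trials x channels x samples for one subject.
#' @return array trials x components x samples.
#' @export
back_reconstruct <- function(decomposition, subject_epochs) {
  if (dim(subject_epochs)[2] != ncol(decomposition$W))
    stop("back_reconstruct: channel count mismatch")
  n_tr <- dim(subject_epochs)[1]
  n_t <- dim(subject_epochs)[3]
  Xs <- epochs_to_matrix(subject_epochs) - decomposition$center
  Cs <- decomposition$W %*% Xs               # k x (trials * samples)
  k <- nrow(Cs)
  dim(Cs) <- c(k, n_t, n_tr)
  aperm(Cs, c(3, 1, 2))
}
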