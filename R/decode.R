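#' Back-project a matched component pair to channel space
#'
#' For one subject, projects the epochs of each condition onto the
#' matched component of that condition's decomposition and back into
#' channel space: the returned tensors are \code{A_k \%o\% C_k} per
#' trial, i.e. rank-1 across channels at every sample. The
#' \code{sign_flip} flag is applied jointly to the incongruent
#' component's topography and activation; the back-projected channel
#' data are invariant under this joint flip (component sign is a pure
#' indeterminacy), so the flag only fixes the reported orientation.
#'
#' @param pair one row of the \code{\link{match_components}} result.
#' @param decomp_cong,decomp_incong the two decompositions.
#' @param epochs an \code{epochs_set}.
#' @param subject subject name (e.g. \code{"sub-01"}).
#' @return list with arrays \code{congruent} and \code{incongruent}
#'   (trials x channels x samples) plus the aligned topography.
#' @export
backproject_pair <- function(pair, decomp_cong, decomp_incong, epochs,
                             subject) {
  if (!subject %in% names(epochs$epochs))
    stop("backproject_pair: unknown subject '", subject, "'")
  one <- function(decomp, k, arr, flip) {
    Cs <- back_reconstruct(decomp, arr)[, k, , drop = FALSE]  # tr x 1 x t
    a <- decomp$A[, k]
    if (flip) { a <- -a; Cs <- -Cs }
    n_tr <- dim(Cs)[1]; n_t <- dim(Cs)[3]
    out <- aperm(outer(a, matrix(Cs, n_tr, n_t)), c(2, 1, 3))
    dimnames(out) <- list(NULL, decomp$channels, NULL)
    list(data = out, topography = a, activation = matrix(Cs, n_tr, n_t))
  }
  cg <- one(decomp_cong, pair$idx_congruent,
            epochs$epochs[[subject]]$congruent, FALSE)
  ig <- one(decomp_incong, pair$idx_incongruent,
            epochs$epochs[[subject]]$incongruent, isTRUE(pair$sign_flip))
  list(congruent = cg$data, incongruent = ig$data,
       topography_congruent = cg$topography,
       topography_incongruent = ig$topography,
       activation_congruent = cg$activation,
       activation_incongruent = ig$activation)
}

# Rank-based AUC of decision values for the positive class (label 1).
decision_auc <- function(dec, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(dec)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Balanced, stratified fold assignment. Returns per-class kept trial
# indices and fold labels; the majority class is under-sampled (seeded)
# to the minority count.
balance_and_fold <- function(n_cong, n_incong, n_folds, seed) {
  set.seed(seed)
  n_keep <- min(n_cong, n_incong)
  if (n_keep < n_folds)
    stop("decode: only ", n_keep, " trials per class after balancing; ",
         "reduce n_folds")
  keep_c <- sort(sample(n_cong, n_keep))
  keep_i <- sort(sample(n_incong, n_keep))
  folds <- sample(rep(seq_len(n_folds), length.out = n_keep))
  list(keep_congruent = keep_c, keep_incongruent = keep_i,
       fold_congruent = folds,
       fold_incongruent = sample(rep(seq_len(n_folds), length.out = n_keep)),
       n_per_class = n_keep)
}

# Shared engine for the diagonal and temporal-generalization analyses.
decode_core <- function(cong, incong, n_folds, seed, generalize,
                        svm_tol = 0.1, svm_max_epochs = 500L) {
  stopifnot(length(dim(cong)) == 3L, length(dim(incong)) == 3L,
            dim(cong)[2] == dim(incong)[2],
            dim(cong)[3] == dim(incong)[3])
  n_t <- dim(cong)[3]
  fb <- balance_and_fold(dim(cong)[1], dim(incong)[1], n_folds, seed)
  Xc <- cong[fb$keep_congruent, , , drop = FALSE]
  Xi <- incong[fb$keep_incongruent, , , drop = FALSE]
  n <- fb$n_per_class

  auc_diag <- matrix(0, n_folds, n_t)
  auc_tg <- if (generalize) array(0, c(n_folds, n_t, n_t)) else NULL

  for (f in seq_len(n_folds)) {
    tr_c <- fb$fold_congruent != f
    tr_i <- fb$fold_incongruent != f
    Xtr <- abind3(Xc[tr_c, , , drop = FALSE], Xi[tr_i, , , drop = FALSE])
    Xte <- abind3(Xc[!tr_c, , , drop = FALSE], Xi[!tr_i, , , drop = FALSE])
    ytr <- c(rep(-1, sum(tr_c)), rep(1, sum(tr_i)))   # +1 = incongruent
    yte_pos <- c(rep(FALSE, sum(!tr_c)), rep(TRUE, sum(!tr_i)))
    # per-(channel, time) standardization by training-fold statistics
    n_tr_f <- dim(Xtr)[1]
    mu <- colMeans(Xtr)                               # ch x t
    sdv <- sqrt(pmax(colMeans(Xtr^2) - mu^2, 0) * n_tr_f / (n_tr_f - 1))
    sdv[sdv < 1e-12] <- 1
    Xtr <- sweep(sweep(Xtr, c(2, 3), mu), c(2, 3), sdv, "/")
    Xte <- sweep(sweep(Xte, c(2, 3), mu), c(2, 3), sdv, "/")
    n_te <- dim(Xte)[1]
    p <- dim(Xtr)[2]
    Xte_flat <- matrix(aperm(Xte, c(1, 3, 2)), n_te * n_t, p)
    for (t in seq_len(n_t)) {
      w <- linsvm_fit(Xtr[, , t], ytr, tol = svm_tol,
                      max_epochs = svm_max_epochs)
      if (generalize) {
        dec_all <- matrix(Xte_flat %*% w[seq_len(p)] + w[p + 1], n_te, n_t)
        auc_tg[f, t, ] <- vapply(seq_len(n_t), function(tt)
          decision_auc(dec_all[, tt], yte_pos), numeric(1))
        auc_diag[f, t] <- auc_tg[f, t, t]
      } else {
        dec <- Xte[, , t] %*% w[seq_len(p)] + w[p + 1]
        auc_diag[f, t] <- decision_auc(dec, yte_pos)
      }
    }
  }
  res <- list(auc_diag = colMeans(auc_diag),
              n_trials_used = c(congruent = n, incongruent = n),
              folds = fb, seed = seed)
  if (generalize) res$auc_tg <- apply(auc_tg, c(2, 3), mean)
  res
}

abind3 <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Time-resolved decoding of congruent vs. incongruent trials
#'
#' Trains one linear maximum-margin classifier (hinge loss, cost 1) per
#' time sample on the 60 channel amplitudes, with the majority class
#' under-sampled to the minority count (seeded), stratified k-fold
#' cross-validation, and features standardized by training-fold
#' statistics. Performance is the decision-value AUC (incongruent as the
#' positive class) computed within each test fold and averaged across
#' folds.
#'
#' @param cong,incong trial tensors (trials x channels x samples).
#' @param n_folds number of cross-validation folds.
#' @param seed seed controlling under-sampling and fold assignment.
#' @param svm_tol,svm_max_epochs stopping controls of the dual
#'   coordinate-descent solver (projected-gradient range tolerance and
#'   epoch cap); the defaults resolve decision-value rankings stably.
#' @return list with \code{auc_diag} (AUC per sample),
#'   \code{n_trials_used}, \code{folds}, \code{seed}.
#' @export
decode_timecourse <- function(cong, incong, n_folds = 5L, seed = 1L,
                              svm_tol = 0.1, svm_max_epochs = 500L) {
  decode_core(cong, incong, n_folds, seed, generalize = FALSE,
              svm_tol = svm_tol, svm_max_epochs = svm_max_epochs)
}

#' Temporal-generalization decoding
#'
#' As \code{\link{decode_timecourse}}, but every classifier trained at
#' \code{t_train} is evaluated at all test times within the same
#' cross-validation split, yielding the AUC matrix indexed
#' \code{[train, test]}. Its diagonal equals the time-resolved analysis
#' under the same seed.
#'
#' @inheritParams decode_timecourse
#' @return list as in \code{\link{decode_timecourse}} plus \code{auc_tg}
#'   (samples x samples matrix).
#' @export
temporal_generalization <- function(cong, incong, n_folds = 5L, seed = 1L,
                                    svm_tol = 0.1, svm_max_epochs = 500L) {
  decode_core(cong, incong, n_folds, seed, generalize = TRUE,
              svm_tol = svm_tol, svm_max_epochs = svm_max_epochs)
}
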