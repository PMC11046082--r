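#' Mean AUC over a significant time window
#'
#' Arithmetic mean of the diagonal decoding AUC over the samples of a
#' pair's significant cluster extent.
#'
#' @param auc_diag AUC per time sample.
#' @param window integer vector of sample indices (a cluster's
#'   \code{cells}).
#' @return scalar mean AUC.
#' @export
mean_auc_in_window <- function(auc_diag, window) {
  if (length(window) == 0L)
    stop("mean_auc_in_window: empty window; skip this pair")
  if (any(window < 1L | window > length(auc_diag)))
    stop("mean_auc_in_window: window indices out of range")
  mean(auc_diag[window])
}

#' Leave-one-out neural-network regression of decoding onto the SSRT
#' congruency effect
#'
#' Feed-forward network (one hidden layer of 5 units, linear output,
#' mild weight decay; \code{nnet}) trained with full-batch optimization
#' and 5 seeded restarts per fit, keeping the restart with the lowest
#' (penalized) training loss. The decay keeps a scalar-input network
#' from contorting between training points when the input carries no
#' information.
#' For each held-out subject the network is trained on all others with
#' inputs and targets standardized by training-set statistics, and the
#' de-standardized prediction is recorded. Accuracy is the RMSE over the
#' held-out predictions, with a subject-level bootstrap 95\% confidence
#' interval.
#'
#' @param inputs per-subject scalar decoding strength (windowed mean AUC).
#' @param targets per-subject SSRT congruency effect
#'   (incongruent - congruent), ms.
#' @param seed seed controlling restart initializations and the bootstrap.
#' @param n_restarts restarts per LOO fit.
#' @param decay weight-decay penalty passed to \code{nnet}.
#' @param n_boot bootstrap resamples for the RMSE interval.
#' @return list with \code{rmse}, \code{rmse_ci} (2.5/97.5 percentiles),
#'   \code{predictions} (data.frame subject / predicted / observed),
#'   \code{squared_errors}, \code{seed}.
#' @export
loo_nn_regression <- function(inputs, targets, seed = 1L, n_restarts = 5L,
                              n_boot = 1000L, decay = 0.01) {
  n <- length(inputs)
  if (length(targets) != n)
    stop("loo_nn_regression: inputs and targets must be paired")
  if (n < 10L) stop("loo_nn_regression: need at least 10 subjects")
  if (!all(is.finite(inputs)) || !all(is.finite(targets)))
    stop("loo_nn_regression: inputs and targets must be finite")
  pred <- numeric(n)
  for (held in seq_len(n)) {
    xtr <- inputs[-held]
    ytr <- targets[-held]
    mx <- mean(xtr); sx <- stats::sd(xtr); if (sx < 1e-12) sx <- 1
    my <- mean(ytr); sy <- stats::sd(ytr); if (sy < 1e-12) sy <- 1
    xs <- (xtr - mx) / sx
    ys <- (ytr - my) / sy
    best <- NULL
    best_loss <- Inf
    for (r in seq_len(n_restarts)) {
      set.seed(seed + 131L * held + r)
      fit <- nnet::nnet(matrix(xs, ncol = 1), ys, size = 5L, linout = TRUE,
                        maxit = 500L, decay = decay, trace = FALSE)
      loss <- fit$value
      if (is.finite(loss) && loss < best_loss) {
        best_loss <- loss
        best <- fit
      }
    }
    if (is.null(best))
      stop("loo_nn_regression: no restart converged (seed ", seed, ")")
    xh <- (inputs[held] - mx) / sx
    pred[held] <- stats::predict(best, matrix(xh, ncol = 1))[1] * sy + my
  }
  err2 <- (pred - targets)^2
  set.seed(seed + 99991L)
  boot <- vapply(seq_len(n_boot), function(b)
    sqrt(mean(err2[sample(n, replace = TRUE)])), numeric(1))
  list(rmse = sqrt(mean(err2)),
       rmse_ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       predictions = data.frame(subject = seq_len(n), predicted = pred,
                                observed = targets),
       squared_errors = err2, seed = seed)
}

#' Compare prediction errors across component pairs
#'
#' Paired two-sided t-tests on the per-subject squared prediction errors
#' between every pair of IC pairs. Identical error vectors are flagged
#' degenerate (p = 1).
#'
#' @param results named list of \code{\link{loo_nn_regression}} outputs,
#'   one per IC pair.
#' @return data.frame with columns \code{pair_a}, \code{pair_b},
#'   \code{t}, \code{p}, \code{degenerate}.
#' @export
compare_rmse <- function(results) {
  if (length(results) < 2L)
    stop("compare_rmse: need at least 2 pairs")
  nms <- names(results)
  if (is.null(nms)) nms <- as.character(seq_along(results))
  out <- list()
  for (i in seq_len(length(results) - 1L)) {
    for (j in (i + 1L):length(results)) {
      d <- results[[i]]$squared_errors - results[[j]]$squared_errors
      if (all(abs(d) < 1e-12) || stats::sd(d) < 1e-12) {
        tt <- list(statistic = 0, p.value = 1)
        deg <- TRUE
      } else {
        tt <- stats::t.test(results[[i]]$squared_errors,
                            results[[j]]$squared_errors, paired = TRUE)
        deg <- FALSE
      }
      out[[length(out) + 1L]] <- data.frame(
        pair_a = nms[i], pair_b = nms[j],
        t = unname(tt$statistic), p = tt$p.value, degenerate = deg,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
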