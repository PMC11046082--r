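#' Ex-Gaussian race-model parameters
#'
#' Parameters of the independent horse-race between the go process and the
#' stop process, one ex-Gaussian finishing-time distribution per congruency
#' condition for each process. The ex-Gaussian (Gaussian plus exponential,
#' mean \code{mu + tau}) is the standard positively skewed RT family.
#' Defaults are tuned so that the generative condition means approximate
#' the behavioral results of the modelled study: mean go finishing time
#' about 494 ms (congruent) and 522 ms (incongruent), mean stop finishing
#' time (true SSRT) about 270 ms (congruent) and 279 ms (incongruent).
#'
#' @param go_mu,go_sigma,go_tau named numeric vectors with elements
#'   \code{congruent} and \code{incongruent}: ex-Gaussian parameters (ms)
#'   of the go-process finishing time.
#' @param ssrt_mu,ssrt_sigma,ssrt_tau same, for the stop-process finishing
#'   time measured from stop-signal onset.
#' @param miss_rate probability that the go process never finishes within
#'   the response window (omission).
#' @param error_rate probability that a finished go process selects the
#'   wrong effector (choice error).
#' @return an object of class \code{race_params}.
#' @export
race_params <- function(go_mu = c(congruent = 393.7, incongruent = 411.57),
                        go_sigma = c(congruent = 45, incongruent = 45),
                        go_tau = c(congruent = 100, incongruent = 110),
                        ssrt_mu = c(congruent = 239.86, incongruent = 249.01),
                        ssrt_sigma = c(congruent = 25, incongruent = 25),
                        ssrt_tau = c(congruent = 30, incongruent = 30),
                        miss_rate = 0.005,
                        error_rate = 0.045) {
  conds <- c("congruent", "incongruent")
  fix <- function(x, nm) {
    if (length(x) == 1L) x <- c(congruent = unname(x), incongruent = unname(x))
    if (!all(conds %in% names(x)))
      stop("race_params: ", nm, " needs elements 'congruent' and 'incongruent'")
    x[conds]
  }
  p <- list(go_mu = fix(go_mu, "go_mu"), go_sigma = fix(go_sigma, "go_sigma"),
            go_tau = fix(go_tau, "go_tau"), ssrt_mu = fix(ssrt_mu, "ssrt_mu"),
            ssrt_sigma = fix(ssrt_sigma, "ssrt_sigma"),
            ssrt_tau = fix(ssrt_tau, "ssrt_tau"),
            miss_rate = miss_rate, error_rate = error_rate)
  if (any(c(p$go_sigma, p$ssrt_sigma) < 0))
    stop("race_params: scale parameters must be non-negative")
  if (any(c(p$go_tau, p$ssrt_tau) < 0))
    stop("race_params: tau must be non-negative")
  if (miss_rate < 0 || miss_rate > 1 || error_rate < 0 || error_rate > 1)
    stop("race_params: probabilities must lie in [0, 1]")
  structure(p, class = "race_params")
}

#' Mean finishing times implied by race parameters
#'
#' @param params a \code{race_params} object.
#' @return list with numeric vectors \code{go} and \code{ssrt}, the
#'   ex-Gaussian means \code{mu + tau} per condition.
#' @export
race_means <- function(params) {
  list(go = params$go_mu + params$go_tau,
       ssrt = params$ssrt_mu + params$ssrt_tau)
}

# Ex-Gaussian deviates: Gaussian(mu, sigma) + Exponential(tau).
rexgauss <- function(n, mu, sigma, tau) {
  x <- stats::rnorm(n, mu, sigma)
  if (tau > 0) x <- x + stats::rexp(n, rate = 1 / tau)
  x
}
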