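#' Sample signals from the generative model
#'
#' Draws one (or more) latent state trajectories from the zero-mean
#' Gaussian process with squared-exponential covariance at the given
#' (time, stimulus) points, then adds independent Gaussian observation
#' noise of variance `alpha` to produce signals. This is the process the
#' filter is optimal for; it backs parameter- and state-recovery checks.
#'
#' The Gram matrix receives a minimal diagonal jitter of `1e-10` before
#' factorization: unlike the posterior solve (regularized by `alpha` on the
#' diagonal), the prior draw factorizes `K` itself, which is numerically
#' singular for closely spaced points.
#'
#' @param times Query times.
#' @param stimulus Stimulus coordinates: single value, length-`D` vector,
#'   or matrix with one row per time point.
#' @param alpha Observation noise variance.
#' @param length_scale Kernel length-scale.
#' @param nsim Number of independent draws.
#' @param seed Integer seed (global RNG state preserved); `NULL` uses the
#'   current stream.
#' @return A list with `latent` and `signals` (`length(times) x nsim`
#'   matrices) and `history`, a [stimulus_protocol()] holding the first
#'   draw's signals.
#' @examples
#' g <- sample_gp_signals(seq(0, 9.8, by = 0.2), seed = 1)
#' fit <- habituate(g$history, condition_on_current = TRUE)
#' mean((fit$posterior$mean - g$latent[, 1])^2)  # < prior variance 1
#' @export
sample_gp_signals <- function(times, stimulus = 0, alpha = 0.3,
                              length_scale = 1, nsim = 1, seed = NULL) {
  if (any(!is.finite(times))) stop("invalid-protocol: times must be finite")
  .check_alpha(alpha)
  .check_length_scale(length_scale)
  n <- length(times)
  if (is.matrix(stimulus)) {
    if (nrow(stimulus) != n) stop("invalid-protocol: stimulus rows != times")
    S <- stimulus
  } else {
    S <- matrix(rep(as.double(stimulus), each = n), nrow = n)
  }
  Z <- cbind(as.double(times), S)
  K <- .se_cross(Z, Z, length_scale)
  K <- (K + t(K)) / 2 + diag(1e-10, n)
  L <- t(chol(K))
  draw <- function() {
    latent <- drop(L %*% stats::rnorm(n))
    list(latent = latent,
         signal = latent + stats::rnorm(n, 0, sqrt(alpha)))
  }
  run <- function() replicate(nsim, draw(), simplify = FALSE)
  draws <- if (is.null(seed)) run() else with_preserved_seed(seed, run())
  latent <- vapply(draws, `[[`, numeric(n), "latent")
  signals <- vapply(draws, `[[`, numeric(n), "signal")
  latent <- matrix(latent, nrow = n)
  signals <- matrix(signals, nrow = n)
  hist <- stimulus_protocol(time = times, signal = signals[, 1L], stimulus = S)
  list(latent = latent, signals = signals, history = hist)
}
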