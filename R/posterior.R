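#' Gaussian-process posterior over the latent state
#'
#' Exact GP regression of the latent stimulus-intensity state on the signal
#' history. With prior mean fixed at 0, unit prior variance, Gram matrix `K`
#' over the history points, covariance vector `k_t` between the query and
#' the history, and observation-noise variance `alpha`, the posterior at a
#' query point is
#' \deqn{\hat{x} = k_t^\top (K + \alpha I)^{-1} h, \qquad
#'       \sigma^2 = k(z, z) - k_t^\top (K + \alpha I)^{-1} k_t,}
#' where `h` is the column of observed signals. An empty history returns the
#' prior (mean 0, variance 1). The linear solves use a Cholesky
#' factorization of `K + alpha I`; no explicit inverse is formed and no
#' extra jitter is added (`alpha > 0` already regularizes the system).
#'
#' @param query Query point(s): a numeric vector `c(time, stimulus...)`, a
#'   matrix with one point per row, or a data frame / protocol with `time`
#'   and `s*` columns.
#' @param history A [stimulus_protocol()] of observed events (probe rows,
#'   i.e. `signal = NA`, are ignored). May be empty.
#' @param alpha Signal noise variance (positive). Default 0.3.
#' @param length_scale Kernel length-scale. Default 1.
#' @return A data frame with one row per query point and columns `mean` and
#'   `variance` (variance clamped to `[0, 1]` against round-off).
#' @examples
#' h <- stimulus_protocol(time = 0, signal = 1)
#' gp_posterior(c(0, 0), h, alpha = 0.3)  # mean 1/1.3, variance 0.3/1.3
#' @export
gp_posterior <- function(query, history, alpha = 0.3, length_scale = 1) {
  .check_alpha(alpha)
  Q <- .as_point_matrix(query)
  if (is.data.frame(history)) history <- history[!is.na(history$signal), , drop = FALSE]
  Z <- .as_point_matrix(history)
  if (nrow(Z) > 0L && ncol(Z) != ncol(Q)) {
    stop("invalid-protocol: query and history have mismatched stimulus dimension")
  }
  n <- nrow(Z)
  if (n == 0L) {
    return(data.frame(mean = rep(0, nrow(Q)), variance = rep(1, nrow(Q))))
  }
  h <- history$signal
  K <- .se_cross(Z, Z, length_scale)
  A <- (K + t(K)) / 2 + diag(alpha, n)
  L <- tryCatch(chol(A), error = function(e) {
    stop("numerical-failure: Cholesky factorization of K + alpha*I failed ",
         "(alpha = ", alpha, ", length_scale = ", length_scale,
         ") for history times [",
         paste(signif(history$time, 6), collapse = ", "), "]")
  })
  kt <- .se_cross(Z, Q, length_scale)            # n x m
  w <- backsolve(L, forwardsolve(t(L), h))       # (K + aI)^{-1} h
  V <- backsolve(L, forwardsolve(t(L), kt))      # (K + aI)^{-1} k_t
  mean <- drop(crossprod(kt, w))
  variance <- 1 - colSums(kt * V)
  data.frame(mean = mean, variance = pmin(pmax(variance, 0), 1))
}

#' Monte-Carlo threshold-exceedance oracle
#'
#' Brute-force estimate of the response: draws from the Gaussian posterior
#' at a query point and returns the fraction of samples exceeding the
#' threshold `psi`. Used as an independent check of the closed-form
#' [response_probability()]; the sampling path shares no code with the
#' normal-CDF evaluation.
#'
#' @inheritParams gp_posterior
#' @param psi Response threshold.
#' @param n_samples Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; the global RNG state is preserved.
#' @return Estimated exceedance probability in `[0, 1]`.
#' @export
mc_exceedance <- function(query, history, alpha = 0.3, psi = 0.5,
                          length_scale = 1, n_samples = 1e5, seed = 1) {
  if (n_samples < 1) stop("invalid-parameter: n_samples must be >= 1")
  post <- gp_posterior(query, history, alpha = alpha, length_scale = length_scale)
  if (nrow(post) != 1L) stop("mc_exceedance expects a single query point")
  draws <- with_preserved_seed(seed,
    stats::rnorm(n_samples, post$mean, sqrt(post$variance)))
  mean(draws > psi)
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("invalid-parameter: alpha must be a single positive number")
  }
}
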