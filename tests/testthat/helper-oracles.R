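# Shared fixtures: randomized histories/queries and the independent
# GP-regression oracle used to cross-check the Cholesky-based posterior.

# Random signal history with n events over [0, t_max] in a D-dimensional
# stimulus space. Times are sorted; signals are standard normal.
random_history <- function(n, D = 1, t_max = 5) {
  stimulus_protocol(time = sort(stats::runif(n, 0, t_max)),
                    signal = stats::rnorm(n),
                    stimulus = matrix(stats::runif(n * D, -1, 1), nrow = n))
}

random_query <- function(D = 1, t_max = 5) {
  c(stats::runif(1, 0, t_max), stats::runif(D, -1, 1))
}

# Independent GP-regression oracle: kernlab's gausspr with an rbf kernel
# (sigma = 1 / (2 * lambda^2)) and noise variance alpha. Returns the
# predictive mean and latent standard deviation at the query points.
kernlab_posterior <- function(query, history, alpha, length_scale) {
  X <- as.matrix(history[, grep("^(time|s[0-9]+)$", names(history))])
  Q <- matrix(query, nrow = 1)
  m <- kernlab::gausspr(X, history$signal, type = "regression",
                        kernel = "rbfdot",
                        kpar = list(sigma = 1 / (2 * length_scale^2)),
                        var = alpha, variance.model = TRUE,
                        scaled = FALSE, tol = 1e-12)
  list(mean = as.numeric(kernlab::predict(m, Q)),
       sd = as.numeric(kernlab::predict(m, Q, type = "sdeviation")))
}
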