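test_that("response probability evaluates the threshold-exceedance rule", {
  expect_equal(response_probability(0.5, 0.25, psi = 0.5), 0.5)
  expect_equal(response_probability(0, 1, psi = 0.5), pnorm(-0.5))
  # mean - psi = sigma gives pnorm(1)
  expect_equal(response_probability(1.3, 0.64, psi = 0.5), pnorm(1))
  # degenerate sigma = 0: indicator with symmetric boundary
  expect_equal(response_probability(c(0.6, 0.4, 0.5), 0, psi = 0.5),
               c(1, 0, 0.5))
  expect_error(response_probability(0, -1), "invalid-parameter")
})

test_that("responses are symmetric around the threshold and monotone", {
  set.seed(31)
  for (i in 1:20) {
    delta <- stats::runif(1, 0, 2)
    s2 <- stats::runif(1, 0.01, 1)
    expect_equal(response_probability(0.5 + delta, s2) +
                   response_probability(0.5 - delta, s2), 1)
  }
  # increasing in the mean at fixed variance
  y <- response_probability(seq(-1, 2, 0.1), 0.4)
  expect_true(all(diff(y) > 0))
  # increasing in sigma below threshold, decreasing above
  v <- seq(0.01, 1, 0.01)
  expect_true(all(diff(response_probability(0.2, v)) > 0))
  expect_true(all(diff(response_probability(0.8, v)) < 0))
})

test_that("an empty protocol with one probe reads out the prior response", {
  fit <- habituate(probe_events(0), normalize = FALSE)
  expect_equal(fit$raw, pnorm(-0.5))
  fit2 <- habituate(probe_events(0), psi = 1.2, normalize = FALSE)
  expect_equal(fit2$raw, pnorm(-1.2))
})

test_that("repetition habituates below threshold and sensitizes above it", {
  hab <- habituate(stimulus_series(10, 0.1, 0.2))
  expect_lt(hab$raw[10], hab$raw[1])
  expect_true(all(diff(hab$raw[-1]) <= 1e-9))
  sens <- habituate(stimulus_series(10, 0.1, 1.0))
  expect_gt(sens$raw[10], sens$raw[1])
})

test_that("the fit is deterministic", {
  pr <- concat_protocols(stimulus_series(6, 0.1, 0.2), probe_events(0), gap = 1)
  f1 <- habituate(pr)
  f2 <- habituate(pr)
  expect_identical(f1$raw, f2$raw)
  expect_identical(f1$posterior, f2$posterior)
})

test_that("conditioning conventions differ only by the current observation", {
  pr <- stimulus_series(5, 0.1, 0.4)
  just_prior <- habituate(pr, normalize = FALSE)
  inclusive <- habituate(pr, condition_on_current = TRUE, normalize = FALSE)
  # just-prior first trial is the prior read-out
  expect_equal(just_prior$raw[1], pnorm(-0.5))
  # inclusive first trial conditions on its own signal: scalar closed form
  m <- 0.4 / 1.3
  s <- sqrt(0.3 / 1.3)
  expect_equal(inclusive$raw[1], pnorm((m - 0.5) / s), tolerance = 1e-12)
  # the inclusive response at trial t equals the just-prior response that a
  # probe at the same point would give after observing trials 1..t
  probe_after <- predict(habituate(pr[1:3, ], normalize = FALSE),
                         c(pr$time[3], 0))
  expect_equal(inclusive$raw[3], probe_after, tolerance = 1e-12)
})

test_that("normalization anchors the isolated stimulus at exactly 100", {
  one <- stimulus_series(1, 1, 0.2)
  expect_identical(habituate(one)$normalized, 100)
  expect_identical(habituate(one, condition_on_current = TRUE)$normalized, 100)
  # linearity: raw = reference/2 maps to 50
  fit <- habituate(stimulus_series(10, 0.1, 0.2))
  expect_equal(fit$normalized, 100 * fit$raw / fit$reference_raw)
  expect_equal(fit$normalized[1], 100)  # just-prior: trial 1 is unhabituated
  # habituation series: starts at 100 and decreases
  expect_lt(fit$normalized[10], 100)
})

test_that("a custom normalization reference rescales the trace", {
  fit <- habituate(stimulus_series(8, 0.1, 0.2))
  ref <- stimulus_protocol(time = 0, signal = 0.9)
  refit <- normalize_trace(fit, ref)
  # just-prior convention: isolated response is the prior response for any
  # reference intensity
  expect_equal(refit$reference_raw, pnorm(-0.5))
  inc <- habituate(stimulus_series(8, 0.1, 0.2), condition_on_current = TRUE)
  re_inc <- normalize_trace(inc, ref)
  expect_equal(re_inc$reference_raw,
               pnorm((0.9 / 1.3 - 0.5) / sqrt(0.3 / 1.3)))
  expect_error(normalize_trace(fit, probe_events(0)), "degenerate-reference")
})

test_that("traces serialize to a flat CSV with stable precision", {
  fit <- habituate(concat_protocols(stimulus_series(5, 0.1, 0.2),
                                    probe_events(0), gap = 0.7))
  path <- tempfile(fileext = ".csv")
  write_trace(fit, path)
  back <- utils::read.csv(path)
  expect_named(back, c("time", "s1", "signal", "posterior_mean",
                       "posterior_variance", "raw", "normalized"))
  expect_equal(nrow(back), 6)
  expect_equal(back$raw, fit$raw, tolerance = 1e-11)
  expect_true(is.na(back$signal[6]))
  # byte-identical on rerun
  path2 <- tempfile(fileext = ".csv")
  write_trace(fit, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("model object methods report the fit", {
  fit <- habituate(stimulus_series(6, 0.1, 0.2))
  expect_equal(coef(fit), c(alpha = 0.3, psi = 0.5, length_scale = 1))
  expect_identical(fitted(fit), fit$raw)
  expect_equal(residuals(fit), fit$protocol$signal - fit$posterior$mean)
  expect_output(print(fit), "Optimal-filtering")
  expect_output(print(summary(fit)), "Response trace")
  df <- as.data.frame(fit)
  expect_equal(df$normalized, fit$normalized)
  post <- predict(fit, c(10, 0), type = "posterior")
  expect_gt(post$variance, 1 - 1e-6)  # far future reverts to the prior
})
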