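# The canonical habituation phenomena, checked under both conditioning
# conventions at the default parameterization (alpha 0.3, psi 0.5,
# lambda 1).

both_conventions <- list(just_prior = hab_params(),
                         inclusive = hab_params(condition_on_current = TRUE))

test_that("all primary phenomena pass at the default parameterization", {
  for (params in both_conventions) {
    expect_true(check_simple_habituation(params)$passed)
    expect_true(check_sensitization(params)$passed)
    expect_true(check_frequency_effect(params)$passed)
    expect_true(check_spontaneous_recovery(params)$passed)
    expect_true(check_below_zero(params)$passed)
    expect_true(check_potentiation(params)$passed)
    expect_true(check_stimulus_specificity(params)$passed)
    expect_true(check_dishabituation(params)$passed)
  }
})

test_that("degenerate protocols are flagged rather than passed", {
  # one trial: vacuous habituation, zero decrement
  r <- check_simple_habituation(n_trials = 1)
  expect_true(r$passed)
  expect_equal(r$metrics$vacuous, 1)
  expect_equal(r$metrics$decrement, 0)
  # intensity at the threshold: the response approaches the boundary value
  # 1/2 from below and never crosses it — the watershed between the
  # habituating and sensitizing regimes
  for (conv in c(FALSE, TRUE)) {
    fit <- habituate(stimulus_series(30, 0.1, 0.5),
                     condition_on_current = conv, normalize = FALSE)
    expect_true(all(fit$raw < 0.5))
    expect_gt(fit$raw[30], pnorm(-0.5))
  }
  # equal intervals: no frequency contrast
  r <- check_frequency_effect(fast_interval = 0.2, slow_interval = 0.2)
  expect_false(r$passed)
  expect_equal(r$metrics$vacuous, 1)
  # equal series lengths: no below-zero contrast
  r <- check_below_zero(short_trials = 10, long_trials = 10)
  expect_false(r$passed)
  expect_equal(r$metrics$vacuous, 1)
  expect_equal(r$metrics$probe_short, r$metrics$probe_long)
})

test_that("potentiation requires genuine recovery before the second series", {
  # no rest: the second series starts far below the first trial's level
  r <- check_potentiation(rest = 0.1)
  expect_false(r$passed)
  expect_equal(r$metrics$precondition_met, 0)
  expect_equal(r$metrics$residual_habituation, 1)
  # searched rest meets the matched-start precondition and rehabituates faster
  r <- check_potentiation()
  expect_true(r$passed)
  expect_equal(r$metrics$precondition_met, 1)
  expect_lte(r$metrics$start_deviation_units, 5)
  # no temporal generalization, no memory across the rest: no potentiation
  r <- check_potentiation(hab_params(length_scale = 0.001))
  expect_false(r$passed)
})

test_that("spontaneous recovery reverts to the prior at long delays", {
  params <- hab_params()
  fit <- habituate(stimulus_series(10, 0.1, 0.2), normalize = FALSE)
  far <- predict(fit, c(0.9 + 50, 0))
  expect_equal(far, pnorm(-0.5), tolerance = 1e-9)
  # delay ~0 continues the series trajectory rather than recovering
  near <- predict(fit, c(0.9 + 1e-6, 0))
  expect_lt(near, fit$raw[10] + 1e-3)
})

test_that("novelty effects are graded and shared between phenomena", {
  # probes far beyond the generalization horizon return to baseline
  fit <- habituate(stimulus_series(10, 0.1, 0.2), normalize = FALSE)
  far_probe <- predict(fit, c(1.0, 50))
  expect_equal(far_probe, pnorm(-0.5), tolerance = 1e-9)
  # a "novel" stimulus identical to the familiar one dishabituates nothing:
  # both arms coincide so the intensity-dependence clause cannot hold
  r <- check_dishabituation(weak_offset = 1e-9, weak_intensity = 0.2,
                            strong_offset = 1e-9, strong_intensity = 0.2)
  expect_false(r$passed)
  expect_equal(r$metrics$intensity_dependence, 0)
  expect_lt(r$metrics$weak_increment_1,
            check_dishabituation()$metrics$weak_increment_1)
  # specificity decrement and dishabituation increment rise together
  rho <- specificity_dishabituation_correlation()
  expect_gt(rho, 0.9)
  grid <- attr(rho, "grid")
  expect_true(all(diff(grid$specificity_decrement) > 0))
})

test_that("length-scale ablations break the predicted phenomena", {
  for (conv in c(FALSE, TRUE)) {
    rough <- hab_params(length_scale = 0.001, condition_on_current = conv)
    expect_false(check_simple_habituation(rough)$passed)
    expect_false(check_sensitization(rough)$passed)
    expect_false(check_frequency_effect(rough)$passed)
    # the flat curve: every response equals the prior read-out
    raw <- habituate(stimulus_series(10, 0.1, 0.2),
                     length_scale = 0.001,
                     condition_on_current = conv, normalize = FALSE)$raw
    if (!conv) expect_equal(raw, rep(pnorm(-0.5), 10), tolerance = 1e-6)

    smooth <- hab_params(length_scale = 100, condition_on_current = conv)
    expect_true(check_simple_habituation(smooth)$passed)
    expect_true(check_sensitization(smooth)$passed)
    expect_false(check_frequency_effect(smooth)$passed)
  }
})

test_that("the battery aggregates the expected pass/fail pattern", {
  bat <- run_battery()
  df <- data.frame(check = vapply(bat, `[[`, character(1), "name"),
                   param = vapply(bat, `[[`, character(1), "parameterization"),
                   passed = vapply(bat, `[[`, logical(1), "passed"))
  expect_equal(nrow(df), 14)
  expect_true(all(df$passed[df$param == "default"]))
  expect_false(any(df$passed[df$param == "lambda=0.001"]))
  l100 <- df[df$param == "lambda=100", ]
  expect_true(all(l100$passed[l100$check != "frequency_effect"]))
  expect_false(l100$passed[l100$check == "frequency_effect"])
  expect_output(print(bat), "phenomena battery")

  path <- tempfile(fileext = ".ndjson")
  write_battery(bat, path)
  lines <- readLines(path)
  expect_length(lines, 14)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$name, "simple_habituation")
  expect_true(rec$passed)
  expect_true(is.numeric(rec$metrics$decrement))
})

test_that("checks hold on a small perturbation of the default protocols", {
  # spot checks of the +/-25% neighborhood (the full grid runs in the
  # acceptance suite)
  expect_true(check_simple_habituation(intensity = 0.25)$passed)
  expect_true(check_frequency_effect(fast_interval = 0.125,
                                     slow_interval = 0.375)$passed)
  expect_true(check_spontaneous_recovery(delays = c(0.375, 0.75, 1.125))$passed)
  expect_true(check_dishabituation(n_trials = 12)$passed)
})
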