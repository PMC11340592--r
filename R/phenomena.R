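#' Model parameters for the habituation filter
#'
#' Bundles the filter's parameters for the phenomena checks. Defaults are
#' the fixed parameterization used throughout: noise variance
#' `alpha = 0.3`, threshold `psi = 0.5`, length-scale `length_scale = 1`.
#'
#' @param alpha Signal noise variance (positive).
#' @param psi Response threshold.
#' @param length_scale Kernel length-scale.
#' @param condition_on_current Conditioning convention (see [habituate()]).
#' @return A list of class `"hab_params"`.
#' @export
hab_params <- function(alpha = 0.3, psi = 0.5, length_scale = 1,
                       condition_on_current = FALSE) {
  .check_alpha(alpha)
  .check_length_scale(length_scale)
  structure(list(alpha = alpha, psi = psi, length_scale = length_scale,
                 condition_on_current = condition_on_current),
            class = "hab_params")
}

.fit <- function(protocol, params, normalize = FALSE) {
  habituate(protocol, alpha = params$alpha, psi = params$psi,
            length_scale = params$length_scale,
            condition_on_current = params$condition_on_current,
            normalize = normalize)
}

# comparison tolerance for strict inequalities between responses
.STRICT <- 1e-9

new_report <- function(name, passed, metrics, protocol_summary) {
  structure(list(name = name, passed = isTRUE(passed),
                 metrics = metrics, protocol_summary = protocol_summary),
            class = "phenomenon_report")
}

#' @export
print.phenomenon_report <- function(x, ...) {
  cat(sprintf("[%s] %s\n  %s\n", if (x$passed) "PASS" else "fail",
              x$name, x$protocol_summary))
  m <- x$metrics
  cat("  ", paste(sprintf("%s=%.5g", names(m), unlist(m)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Simple habituation: progressive response decrement to repetition
#'
#' Repeated sub-threshold stimulation must produce a progressive decrease
#' in the raw response toward an asymptote. The check passes when the total
#' first-to-final decrement exceeds `min_decrement` and the responses after
#' trial 1 are non-increasing, tolerating trial-to-trial upticks no larger
#' than 1% of the total decrement (the learning curves are not perfectly
#' monotone at coarser stimulation; see the package vignette).
#'
#' @param params A [hab_params()] bundle.
#' @param n_trials,interval,intensity Series specification (see
#'   [stimulus_series()]). Intensity should be below the threshold.
#' @param min_decrement Minimal raw first-to-final decrement to count as
#'   habituation (also what makes the flat short-length-scale curves fail).
#' @return A `phenomenon_report`.
#' @examples
#' check_simple_habituation()$passed            # TRUE at defaults
#' check_simple_habituation(hab_params(length_scale = 0.001))$passed  # flat
#' @export
check_simple_habituation <- function(params = hab_params(), n_trials = 10,
                                     interval = 0.1, intensity = 0.2,
                                     min_decrement = 1e-3) {
  raw <- .fit(stimulus_series(n_trials, interval, intensity), params)$raw
  summary_txt <- sprintf("series n=%d interval=%g intensity=%g lambda=%g",
                         n_trials, interval, intensity, params$length_scale)
  if (n_trials == 1L) {
    return(new_report("simple_habituation", TRUE,
                      list(first = raw[1], final = raw[1], decrement = 0,
                           vacuous = 1), summary_txt))
  }
  decrement <- raw[1] - raw[n_trials]
  steps <- diff(raw[-1])
  tol <- max(.STRICT, 0.01 * decrement)
  passed <- decrement > min_decrement && all(steps <= tol)
  new_report("simple_habituation", passed,
             list(first = raw[1], final = raw[n_trials],
                  decrement = decrement,
                  max_increase_after_trial1 = max(c(steps, -Inf)),
                  vacuous = 0),
             summary_txt)
}

#' Sensitization: increased responding for supra-threshold repetition
#'
#' When the repeated intensity exceeds the threshold, responding must
#' increase with repetition (final raw response above the first by more
#' than `min_increment`). At the boundary `intensity == psi` the curve is
#' flat and the check reports without passing.
#'
#' @inheritParams check_simple_habituation
#' @param min_increment Minimal raw final-over-first increase.
#' @return A `phenomenon_report`.
#' @export
check_sensitization <- function(params = hab_params(), n_trials = 10,
                                interval = 0.1, intensity = 1.0,
                                min_increment = 1e-3) {
  raw <- .fit(stimulus_series(n_trials, interval, intensity), params)$raw
  increment <- raw[n_trials] - raw[1]
  new_report("sensitization", increment > min_increment,
             list(first = raw[1], final = raw[n_trials], increment = increment),
             sprintf("series n=%d interval=%g intensity=%g lambda=%g",
                     n_trials, interval, intensity, params$length_scale))
}

#' Frequency sensitivity of habituation and sensitization
#'
#' More frequent stimulation must produce stronger habituation below the
#' threshold (lower final response for the fast series) and stronger
#' sensitization above it (higher final response for the fast series).
#' Both directions must hold by more than `margin`; with a very long
#' length-scale the interval differences become invisible to the filter
#' and the check fails, as predicted.
#'
#' @inheritParams check_simple_habituation
#' @param fast_interval,slow_interval The two inter-stimulus intervals.
#' @param low_intensity,high_intensity Sub- and supra-threshold series
#'   intensities.
#' @param margin Minimal raw-response separation for each direction.
#' @return A `phenomenon_report`.
#' @export
check_frequency_effect <- function(params = hab_params(), n_trials = 10,
                                   fast_interval = 0.1, slow_interval = 0.3,
                                   low_intensity = 0.2, high_intensity = 1.0,
                                   margin = 1e-3) {
  fin <- function(interval, intensity) {
    raw <- .fit(stimulus_series(n_trials, interval, intensity), params)$raw
    raw[n_trials]
  }
  summary_txt <- sprintf(
    "n=%d fast=%g slow=%g low=%g high=%g lambda=%g",
    n_trials, fast_interval, slow_interval, low_intensity, high_intensity,
    params$length_scale)
  if (fast_interval == slow_interval) {
    return(new_report("frequency_effect", FALSE,
                      list(vacuous = 1, hab_separation = 0, sens_separation = 0),
                      summary_txt))
  }
  hab_sep <- fin(slow_interval, low_intensity) - fin(fast_interval, low_intensity)
  sens_sep <- fin(fast_interval, high_intensity) - fin(slow_interval, high_intensity)
  new_report("frequency_effect", hab_sep > margin && sens_sep > margin,
             list(hab_separation = hab_sep, sens_separation = sens_sep,
                  vacuous = 0), summary_txt)
}

#' Spontaneous recovery after a stimulus-free rest
#'
#' After a habituation series, single test probes at increasing delays
#' (each a fresh read-out contributing no observation) must yield
#' responses that increase with delay and exceed the end-of-series
#' response. As the delay grows far beyond the length-scale the probe
#' reverts to the prior response.
#'
#' @inheritParams check_simple_habituation
#' @param delays Positive probe delays after the last trial, increasing.
#' @return A `phenomenon_report`.
#' @export
check_spontaneous_recovery <- function(params = hab_params(), n_trials = 10,
                                       interval = 0.1, intensity = 0.2,
                                       delays = c(0.5, 1, 1.5)) {
  stopifnot(length(delays) >= 2L, all(delays > 0), !is.unsorted(delays))
  fit <- .fit(stimulus_series(n_trials, interval, intensity), params)
  end_time <- (n_trials - 1) * interval
  probes <- predict(fit, data.frame(time = end_time + delays, s1 = 0))
  end_resp <- fit$raw[n_trials]
  passed <- all(diff(probes) > .STRICT) && all(probes > end_resp + .STRICT)
  metrics <- as.list(c(end_response = end_resp,
                       stats::setNames(probes, paste0("probe_", seq_along(probes)))))
  new_report("spontaneous_recovery", passed, metrics,
             sprintf("series n=%d interval=%g intensity=%g; delays %s",
                     n_trials, interval, intensity,
                     paste(delays, collapse = ",")))
}

#' Below-zero habituation: stimulation past asymptote delays recovery
#'
#' Two series identical except for length, both past the response
#' asymptote, are probed once at the same delay after their last trial.
#' The longer series must yield the lower probe response: extra
#' stimulation keeps reducing the posterior variance even after the
#' response has flattened. The default series is denser than the other
#' checks' (interval 0.075) because the accumulated-variance effect only
#' dominates the early phase of recovery when stimulation is dense
#' relative to the length-scale.
#'
#' @inheritParams check_simple_habituation
#' @param short_trials,long_trials Series lengths (`long_trials` well past
#'   asymptote).
#' @param delay Common probe delay after each series' final trial.
#' @param asymptote_tol Trialwise raw change below which the response is
#'   considered asymptotic (reported in the metrics).
#' @return A `phenomenon_report`.
#' @export
check_below_zero <- function(params = hab_params(), short_trials = 10,
                             long_trials = 40, interval = 0.075,
                             intensity = 0.2, delay = 0.3,
                             asymptote_tol = 1e-3) {
  probe <- function(n) {
    fit <- .fit(stimulus_series(n, interval, intensity), params)
    list(p = predict(fit, c((n - 1) * interval + delay, 0)),
         step = abs(diff(utils::tail(fit$raw, 2L))))
  }
  s <- probe(short_trials); l <- probe(long_trials)
  summary_txt <- sprintf("short=%d long=%d interval=%g intensity=%g delay=%g",
                         short_trials, long_trials, interval, intensity, delay)
  if (short_trials == long_trials) {
    return(new_report("below_zero", FALSE,
                      list(vacuous = 1, probe_short = s$p, probe_long = l$p),
                      summary_txt))
  }
  new_report("below_zero", s$p > l$p + .STRICT,
             list(probe_short = s$p, probe_long = l$p,
                  difference = s$p - l$p,
                  short_at_asymptote = as.numeric(s$step < asymptote_tol),
                  long_at_asymptote = as.numeric(l$step < asymptote_tol),
                  vacuous = 0),
             summary_txt)
}

#' Potentiation of habituation: faster rehabituation after recovery
#'
#' A second stimulus series after an adequate rest must start at roughly
#' the first series' starting response level (within `precondition_tol`
#' normalized units) yet rehabituate faster: its responses on early trials
#' 2..5 sit below the first series' responses on the same trials. If
#' `rest = NULL` the rest is chosen by search: the smallest grid value
#' from which the first-trial deviation has settled below `settle_tol`
#' normalized units for all longer rests, i.e. the response has genuinely
#' recovered rather than transiently crossing the baseline.
#'
#' @inheritParams check_simple_habituation
#' @param rest Rest period between the series; `NULL` to search.
#' @param precondition_tol Allowed deviation (normalized units) between the
#'   two series' first-trial responses.
#' @param settle_tol Search criterion (normalized units) for a settled
#'   recovery.
#' @param rest_grid Candidate rests for the search.
#' @return A `phenomenon_report`.
#' @export
check_potentiation <- function(params = hab_params(), n_trials = 10,
                               interval = 0.1, intensity = 0.2, rest = NULL,
                               precondition_tol = 5, settle_tol = 0.02,
                               rest_grid = seq(1, 8, by = 0.25)) {
  stopifnot(n_trials >= 5L)
  s1 <- stimulus_series(n_trials, interval, intensity)
  run <- function(r) {
    .fit(concat_protocols(s1, s1, gap = r), params, normalize = TRUE)
  }
  deviation <- function(fit) {
    100 * abs(fit$raw[n_trials + 1L] - fit$raw[1L]) / fit$reference_raw
  }
  searched <- is.null(rest)
  if (searched) {
    fits <- lapply(rest_grid, run)
    devs <- vapply(fits, deviation, numeric(1))
    settled <- rev(cumprod(rev(devs <= settle_tol))) == 1
    if (!any(settled)) {
      return(new_report("potentiation", FALSE,
                        list(search_failed = 1, min_deviation = min(devs)),
                        sprintf("rest search failed on [%g, %g]; lambda=%g",
                                min(rest_grid), max(rest_grid),
                                params$length_scale)))
    }
    i <- which(settled)[1L]
    rest <- rest_grid[i]
    fit <- fits[[i]]
  } else {
    fit <- run(rest)
  }
  dev <- deviation(fit)
  k <- 2:5
  diffs <- fit$raw[n_trials + k] - fit$raw[k]
  precondition <- dev <= precondition_tol
  passed <- precondition && all(diffs < -.STRICT)
  metrics <- as.list(c(rest = rest, start_deviation_units = dev,
                       precondition_met = as.numeric(precondition),
                       residual_habituation = as.numeric(
                         !precondition &&
                           fit$raw[n_trials + 1L] < fit$raw[1L]),
                       stats::setNames(diffs, paste0("trial", k, "_diff")),
                       search_failed = 0))
  new_report("potentiation", passed, metrics,
             sprintf("two series n=%d interval=%g intensity=%g rest=%g%s",
                     n_trials, interval, intensity, rest,
                     if (searched) " (searched)" else ""))
}

#' Stimulus specificity: graded generalization decrement
#'
#' After habituation to one stimulus, probes at increasing distances in
#' stimulus space must show graded recovery: probe responses increase with
#' offset, all exceed the continued-habituation response at the familiar
#' stimulus, and the farthest probe stays at or below the unhabituated
#' baseline. Probes contribute no observation, so their unhabituated
#' baseline is the prior read-out `pnorm(-psi)` (empty history) under
#' either conditioning convention.
#'
#' @inheritParams check_simple_habituation
#' @param offsets Increasing positive stimulus-space offsets of the probes.
#' @return A `phenomenon_report`.
#' @export
check_stimulus_specificity <- function(params = hab_params(), n_trials = 10,
                                       interval = 0.1, intensity = 0.2,
                                       offsets = c(0.2, 0.4, 0.6)) {
  stopifnot(length(offsets) >= 2L, all(offsets > 0), !is.unsorted(offsets))
  fit <- .fit(stimulus_series(n_trials, interval, intensity), params)
  probe_time <- (n_trials - 1) * interval + interval
  habituated <- predict(fit, c(probe_time, 0))
  probes <- predict(fit, data.frame(time = probe_time, s1 = offsets))
  reference <- response_probability(0, 1, params$psi)
  passed <- all(diff(probes) > .STRICT) &&
    all(probes > habituated + .STRICT) &&
    probes[length(probes)] <= reference + .STRICT
  metrics <- as.list(c(habituated = habituated, reference = reference,
                       stats::setNames(probes, paste0("probe_", seq_along(probes)))))
  new_report("stimulus_specificity", passed, metrics,
             sprintf("series n=%d interval=%g intensity=%g; offsets %s",
                     n_trials, interval, intensity,
                     paste(offsets, collapse = ",")))
}

#' Dishabituation and its habituation
#'
#' After habituation to a familiar stimulus, a novel stimulus is presented
#' and the familiar stimulus probed after each presentation. The check
#' requires (a) the familiar-probe response to rise after the first novel
#' presentation, (b) the strong/far novel stimulus to produce a larger
#' first increase than the weak/near one, and (c) the increment
#' attributable to each successive novel presentation to shrink
#' (habituation of dishabituation). Increments are measured probe-to-probe
#' so that the dishabituating effect is isolated from ongoing
#' familiar-stimulus dynamics.
#'
#' Stimulus-space position follows the coordinate-equals-intensity
#' convention: the familiar stimulus sits at coordinate
#' `familiar_intensity` and a novel stimulus of intensity `I` at
#' coordinate `familiar_intensity + offset` with, by default,
#' `offset = I - familiar_intensity` — a stronger stimulus is farther away
#' in stimulus space.
#'
#' @inheritParams check_simple_habituation
#' @param familiar_intensity Intensity (and coordinate) of the familiar
#'   stimulus.
#' @param weak_offset,weak_intensity Stimulus-space offset and intensity of
#'   the weak/near novel stimulus.
#' @param strong_offset,strong_intensity Offset and intensity of the
#'   strong/far novel stimulus.
#' @param n_novel Number of repeated novel presentations.
#' @return A `phenomenon_report`.
#' @export
check_dishabituation <- function(params = hab_params(), n_trials = 10,
                                 interval = 0.1, familiar_intensity = 0.2,
                                 weak_offset = 0.25, weak_intensity = 0.45,
                                 strong_offset = 0.7, strong_intensity = 0.9,
                                 n_novel = 3) {
  stopifnot(n_novel >= 1L)
  fam_s <- familiar_intensity
  arm <- function(offset, nov_intensity) {
    blocks <- list(stimulus_series(n_trials, interval, familiar_intensity,
                                   stimulus = fam_s),
                   probe_events(0, stimulus = fam_s))
    for (j in seq_len(n_novel)) {
      blocks <- c(blocks,
                  list(stimulus_protocol(0, nov_intensity, fam_s + offset),
                       probe_events(0, stimulus = fam_s)))
    }
    pr <- concat_protocols(blocks, gap = interval)
    fit <- .fit(pr, params)
    fit$raw[is_probe(pr)]        # pre-novel probe, then one per novel
  }
  weak <- arm(weak_offset, weak_intensity)
  strong <- arm(strong_offset, strong_intensity)
  inc_w <- diff(weak)
  inc_s <- diff(strong)
  a <- inc_w[1L] > .STRICT && inc_s[1L] > .STRICT
  b <- inc_s[1L] > inc_w[1L] + .STRICT
  c_ <- if (n_novel >= 2L) {
    all(diff(inc_w) < -.STRICT) && all(diff(inc_s) < -.STRICT)
  } else TRUE
  metrics <- as.list(c(
    stats::setNames(inc_w, paste0("weak_increment_", seq_along(inc_w))),
    stats::setNames(inc_s, paste0("strong_increment_", seq_along(inc_s))),
    dishabituation = as.numeric(a), intensity_dependence = as.numeric(b),
    habituation_of_dishabituation = as.numeric(c_)))
  new_report("dishabituation", a && b && c_, metrics,
             sprintf(paste0("series n=%d interval=%g familiar=%g; ",
                            "weak (off %g, int %g) strong (off %g, int %g) x%d"),
                     n_trials, interval, familiar_intensity, weak_offset,
                     weak_intensity, strong_offset, strong_intensity, n_novel))
}

#' Correlation between stimulus specificity and dishabituation
#'
#' The filter predicts the two multi-stimulus phenomena share a mechanism
#' (generalization decrement through the stimulus-space kernel), so across
#' a grid of novel-stimulus offsets the specificity decrement and the
#' dishabituation increment should be positively correlated. Novel
#' intensities follow the coordinate-equals-intensity convention.
#'
#' @inheritParams check_dishabituation
#' @param offsets Grid of stimulus-space offsets to correlate over.
#' @return Pearson correlation across the offset grid, with the per-offset
#'   measurements attached as attribute `"grid"`.
#' @export
specificity_dishabituation_correlation <- function(params = hab_params(),
                                                   n_trials = 10,
                                                   interval = 0.1,
                                                   familiar_intensity = 0.2,
                                                   offsets = seq(0.2, 0.7, 0.1)) {
  fam_s <- familiar_intensity
  fit <- .fit(stimulus_series(n_trials, interval, familiar_intensity,
                              stimulus = fam_s), params)
  probe_time <- (n_trials - 1) * interval + interval
  habituated <- predict(fit, data.frame(time = probe_time, s1 = fam_s))
  spec_dec <- vapply(offsets, function(o) {
    predict(fit, data.frame(time = probe_time, s1 = fam_s + o)) - habituated
  }, numeric(1))
  dishab <- vapply(offsets, function(o) {
    r <- check_dishabituation(params, n_trials = n_trials, interval = interval,
                              familiar_intensity = familiar_intensity,
                              weak_offset = o, weak_intensity = fam_s + o,
                              strong_offset = o, strong_intensity = fam_s + o,
                              n_novel = 1)
    r$metrics$weak_increment_1
  }, numeric(1))
  out <- stats::cor(spec_dec, dishab)
  attr(out, "grid") <- data.frame(offset = offsets,
                                  specificity_decrement = spec_dec,
                                  dishabituation_increment = dishab)
  out
}

#' Run the full phenomena battery
#'
#' Executes every phenomenon check at the default protocols, then re-runs
#' the frequency-and-intensity checks (simple habituation, sensitization,
#' frequency effect) under the two length-scale ablations
#' `length_scale = 0.001` (no generalization across time: habituation and
#' sensitization disappear) and `length_scale = 100` (near-constant
#' covariance: intensity dependence survives, frequency dependence
#' disappears).
#'
#' @param params A [hab_params()] bundle for the primary runs.
#' @param ablations Run the length-scale ablations? Default `TRUE`.
#' @return A list of `phenomenon_report`s of class `"phenomena_battery"`;
#'   each report carries a `parameterization` field.
#' @examples
#' \donttest{
#' bat <- run_battery()
#' print(bat)
#' }
#' @export
run_battery <- function(params = hab_params(), ablations = TRUE) {
  tag <- function(report, label) {
    report$parameterization <- label
    report
  }
  primary <- list(check_simple_habituation(params),
                  check_sensitization(params),
                  check_frequency_effect(params),
                  check_spontaneous_recovery(params),
                  check_below_zero(params),
                  check_potentiation(params),
                  check_stimulus_specificity(params),
                  check_dishabituation(params))
  out <- lapply(primary, tag, label = "default")
  if (ablations) {
    for (ls in c(0.001, 100)) {
      p <- hab_params(alpha = params$alpha, psi = params$psi,
                      length_scale = ls,
                      condition_on_current = params$condition_on_current)
      label <- sprintf("lambda=%g", ls)
      out <- c(out, list(tag(check_simple_habituation(p), label),
                         tag(check_sensitization(p), label),
                         tag(check_frequency_effect(p), label)))
    }
  }
  structure(out, class = "phenomena_battery")
}

#' @export
print.phenomena_battery <- function(x, ...) {
  df <- data.frame(
    check = vapply(x, `[[`, character(1), "name"),
    parameterization = vapply(x, `[[`, character(1), "parameterization"),
    passed = vapply(x, `[[`, logical(1), "passed"))
  cat("Habituation phenomena battery\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize a battery to line-delimited JSON
#'
#' One JSON record per check: name, parameterization, passed, metrics and
#' the protocol summary.
#'
#' @param battery A `"phenomena_battery"` (or list of reports).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_battery <- function(battery, file) {
  lines <- vapply(battery, function(r) {
    jsonlite::toJSON(list(name = r$name,
                          parameterization = r$parameterization,
                          passed = r$passed,
                          metrics = r$metrics,
                          protocol = r$protocol_summary),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
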