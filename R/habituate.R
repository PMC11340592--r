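#' Threshold-exceedance response probability
#'
#' Maps a posterior estimate of the latent state to a response:
#' \deqn{y = \Phi\!\left(\frac{\hat{x} - \psi}{\sigma}\right),}
#' the posterior probability that the state exceeds the salience threshold
#' `psi`. Interpretable as the probability of a binary action or the
#' amplitude of a continuous one. For `variance = 0` the degenerate limit
#' is the indicator `mean > psi`, with `mean == psi` mapping to 0.5 (the
#' symmetric limit of the normal CDF).
#'
#' @param mean Posterior mean(s) of the latent state.
#' @param variance Posterior variance(s), `>= 0`. Recycled against `mean`.
#' @param psi Response threshold.
#' @return Response value(s) in `[0, 1]`.
#' @examples
#' response_probability(0, 1, psi = 0.5)  # prior response pnorm(-0.5)
#' @export
response_probability <- function(mean, variance, psi = 0.5) {
  n <- max(length(mean), length(variance))
  mean <- rep_len(mean, n)
  variance <- rep_len(variance, n)
  if (any(variance < 0)) stop("invalid-parameter: variance must be >= 0")
  y <- numeric(n)
  pos <- variance > 0
  y[pos] <- stats::pnorm((mean[pos] - psi) / sqrt(variance[pos]))
  y[!pos] <- ifelse(mean[!pos] > psi, 1, ifelse(mean[!pos] < psi, 0, 0.5))
  y
}

#' Fit the optimal-filtering model of habituation to a stimulus protocol
#'
#' Runs the Bayes-optimal filter over a protocol: for each row, the GP
#' posterior over the latent state is computed from the preceding signal
#' history and mapped to a response via the threshold-exceedance rule
#' ([response_probability()]). The trial-by-trial response trace is the
#' quantity plotted in habituation experiments.
#'
#' By default (`condition_on_current = FALSE`) the response at an event is
#' read out *just prior* to that event's signal, i.e. the posterior
#' conditions on strictly earlier rows; with `condition_on_current = TRUE`
#' the event's own signal is included in its history. Probe rows
#' (`signal = NA`) never contribute observations under either convention.
#' The fit is fully deterministic: events carry their intensities verbatim
#' and no observation noise is sampled (the generative mode lives in
#' [sample_gp_signals()]).
#'
#' Responses are also normalized to an unhabituated reference: multiplied
#' by 100 and divided by the response the same model gives to the reference
#' stimulus presented in isolation (by default the protocol's first event),
#' so an isolated stimulus scores exactly 100.
#'
#' @param protocol A [stimulus_protocol()] (time-ordered events, optional
#'   probe rows).
#' @param alpha Signal noise variance, `> 0`. Default 0.3.
#' @param psi Response threshold. Default 0.5.
#' @param length_scale Kernel length-scale `lambda`. Default 1.
#' @param condition_on_current Should the response at an event condition on
#'   that event's own signal? Default `FALSE`.
#' @param reference Optional one-row protocol (or event row) defining the
#'   isolated stimulus used for normalization; defaults to the protocol's
#'   first non-probe event. Set `normalize = FALSE` to skip normalization.
#' @param normalize Compute normalized responses? Default `TRUE`.
#' @return An object of class `"habituation"`: a list with the protocol,
#'   the parameters, the per-row posterior (`mean`, `variance`), raw
#'   responses `raw`, normalized responses `normalized`, and
#'   `reference_raw`. Supports `print`, `summary`, `coef`, `fitted`,
#'   `predict`, `residuals`, `simulate`, `plot` and `as.data.frame`.
#' @examples
#' fit <- habituate(stimulus_series(10, 0.1, 0.2))
#' fitted(fit)                # raw responses, progressively decreasing
#' fit$normalized             # 100 at trial 1, then habituation
#' @export
habituate <- function(protocol, alpha = 0.3, psi = 0.5, length_scale = 1,
                      condition_on_current = FALSE, reference = NULL,
                      normalize = TRUE) {
  protocol <- validate_protocol(protocol)
  .check_alpha(alpha)
  .check_length_scale(length_scale)
  n <- nrow(protocol)
  post <- data.frame(mean = numeric(n), variance = numeric(n))
  obs <- !is_probe(protocol)
  for (i in seq_len(n)) {
    keep <- if (condition_on_current) obs & seq_len(n) <= i else obs & seq_len(n) < i
    post[i, ] <- gp_posterior(protocol[i, , drop = FALSE],
                              protocol[keep, , drop = FALSE],
                              alpha = alpha, length_scale = length_scale)
  }
  raw <- response_probability(post$mean, post$variance, psi)
  fit <- structure(
    list(protocol = protocol, alpha = alpha, psi = psi,
         length_scale = length_scale,
         condition_on_current = condition_on_current,
         posterior = post, raw = raw,
         normalized = NULL, reference_raw = NULL, reference = NULL),
    class = "habituation")
  if (normalize) fit <- normalize_trace(fit, reference) else fit
}

#' Normalize a response trace against an isolated reference stimulus
#'
#' Recomputes the normalization of a fitted trace: the reference response is
#' the raw response of a *fresh* model (same parameters and conditioning
#' convention) to a protocol containing only the reference event; normalized
#' responses are `100 * raw / reference_raw`, so the isolated reference
#' stimulus itself scores exactly 100.
#'
#' @param object A fitted `"habituation"` object.
#' @param reference One-row protocol or event row; defaults to the fitted
#'   protocol's first non-probe event.
#' @return The object with `normalized`, `reference_raw` and `reference`
#'   filled in.
#' @export
normalize_trace <- function(object, reference = NULL) {
  stopifnot(inherits(object, "habituation"))
  if (is.null(reference)) {
    ev <- which(!is_probe(object$protocol))
    if (length(ev) == 0L) {
      stop("degenerate-reference: protocol has no events to normalize against")
    }
    reference <- object$protocol[ev[1L], , drop = FALSE]
  }
  reference <- validate_protocol(as.data.frame(reference))
  if (nrow(reference) != 1L || is.na(reference$signal[1L])) {
    stop("degenerate-reference: reference must be a single non-probe event")
  }
  class(reference) <- c("stimulus_protocol", "data.frame")
  iso <- habituate(reference, alpha = object$alpha, psi = object$psi,
                   length_scale = object$length_scale,
                   condition_on_current = object$condition_on_current,
                   normalize = FALSE)
  ref_raw <- iso$raw[1L]
  if (ref_raw <= 0) {
    stop("degenerate-reference: isolated reference response is zero")
  }
  object$reference <- reference
  object$reference_raw <- ref_raw
  object$normalized <- 100 * (object$raw / ref_raw)
  object
}

#' @export
print.habituation <- function(x, ...) {
  cat("Optimal-filtering habituation model\n")
  cat(sprintf("  alpha = %g, psi = %g, length_scale = %g, conditioning = %s\n",
              x$alpha, x$psi, x$length_scale,
              if (x$condition_on_current) "inclusive" else "just-prior"))
  cat(sprintf("  protocol: %d events, %d probes\n",
              sum(!is_probe(x$protocol)), sum(is_probe(x$protocol))))
  if (length(x$raw)) {
    cat(sprintf("  raw response: first %.4f, final %.4f\n",
                x$raw[1L], x$raw[length(x$raw)]))
    if (!is.null(x$normalized)) {
      cat(sprintf("  normalized: first %.1f, final %.1f (reference %.4f)\n",
                  x$normalized[1L], x$normalized[length(x$normalized)],
                  x$reference_raw))
    }
  }
  invisible(x)
}

#' @export
summary.habituation <- function(object, ...) {
  tr <- as.data.frame(object)
  structure(list(params = coef(object),
                 condition_on_current = object$condition_on_current,
                 n_events = sum(!is_probe(object$protocol)),
                 n_probes = sum(is_probe(object$protocol)),
                 reference_raw = object$reference_raw,
                 trace = tr),
            class = "summary.habituation")
}

#' @export
print.summary.habituation <- function(x, ...) {
  cat("Optimal-filtering habituation model\n\nParameters:\n")
  print(x$params)
  cat(sprintf("\nConditioning: %s; %d events, %d probes\n",
              if (x$condition_on_current) "inclusive" else "just-prior",
              x$n_events, x$n_probes))
  if (!is.null(x$reference_raw)) {
    cat(sprintf("Reference (isolated-stimulus) response: %.6f\n", x$reference_raw))
  }
  cat("\nResponse trace:\n")
  print(utils::head(x$trace, 12L), row.names = FALSE)
  if (nrow(x$trace) > 12L) cat("... (", nrow(x$trace) - 12L, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
coef.habituation <- function(object, ...) {
  c(alpha = object$alpha, psi = object$psi, length_scale = object$length_scale)
}

#' @export
fitted.habituation <- function(object, ...) object$raw

#' Posterior and response at new query points
#'
#' Evaluates the fitted filter at arbitrary time-stimulus points,
#' conditioning on the protocol's full signal history (all non-probe
#' events). This is how delayed recovery probes or generalization probes at
#' novel stimuli are read out.
#'
#' @param object A fitted `"habituation"` object.
#' @param newdata Query points: data frame with `time` and `s*` columns, a
#'   matrix (first column time), or a numeric vector for a single point.
#' @param type `"response"` (default) for threshold-exceedance responses,
#'   `"posterior"` for the posterior mean and variance.
#' @param ... Unused.
#' @return A numeric vector of responses, or a data frame of posteriors.
#' @export
predict.habituation <- function(object, newdata,
                                type = c("response", "posterior"), ...) {
  type <- match.arg(type)
  events <- object$protocol[!is_probe(object$protocol), , drop = FALSE]
  post <- gp_posterior(newdata, events, alpha = object$alpha,
                       length_scale = object$length_scale)
  if (type == "posterior") post
  else response_probability(post$mean, post$variance, object$psi)
}

#' @export
residuals.habituation <- function(object, ...) {
  object$protocol$signal - object$posterior$mean
}

#' Draw signals from the model's own generative process
#'
#' Samples latent states from the zero-mean GP prior at the fitted
#' protocol's (time, stimulus) points and corrupts them with independent
#' Gaussian observation noise of variance `alpha` — the generative
#' counterpart of the filter, used for parameter- and state-recovery
#' checks. See [sample_gp_signals()] for the standalone generator.
#'
#' @param object A fitted `"habituation"` object.
#' @param nsim Number of replicate signal vectors.
#' @param seed Integer seed (global RNG state preserved); `NULL` uses the
#'   current RNG stream.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of signals, one row per
#'   protocol row; the latent draws are attached as attribute `"latent"`.
#' @export
simulate.habituation <- function(object, nsim = 1, seed = NULL, ...) {
  g <- sample_gp_signals(times = object$protocol$time,
                         stimulus = as.matrix(
                           object$protocol[, grep("^s[0-9]+$", names(object$protocol)),
                                           drop = FALSE]),
                         alpha = object$alpha,
                         length_scale = object$length_scale,
                         nsim = nsim, seed = seed)
  out <- as.data.frame(g$signals)
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "latent") <- g$latent
  out
}

#' @export
as.data.frame.habituation <- function(x, ...) {
  out <- as.data.frame(x$protocol)
  out$posterior_mean <- x$posterior$mean
  out$posterior_variance <- x$posterior$variance
  out$raw <- x$raw
  if (!is.null(x$normalized)) out$normalized <- x$normalized
  out
}

#' Write a response trace as a flat CSV table
#'
#' One row per protocol row: time, stimulus coordinates, signal, posterior,
#' raw and normalized response, written with 12 significant digits so that
#' reruns of the same configuration are byte-identical.
#'
#' @param object A fitted `"habituation"` object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_trace <- function(object, file) {
  tr <- as.data.frame(object)
  num <- vapply(tr, is.numeric, logical(1))
  tr[num] <- lapply(tr[num], function(v) {
    ifelse(is.na(v), NA, sprintf("%.12g", v))
  })
  utils::write.csv(tr, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Plot a habituation response trace
#'
#' Stimulus intensities as dots, the response threshold as a dashed line
#' (both on the signal scale, left axis) and the raw response curve.
#'
#' @param x A fitted `"habituation"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.habituation <- function(x, ...) {
  pr <- x$protocol
  ylim <- range(c(0, 1, pr$signal, x$psi), na.rm = TRUE)
  graphics::plot(pr$time, x$raw, type = "b", pch = 16, ylim = ylim,
                 xlab = "time", ylab = "response / signal", ...)
  ev <- !is_probe(pr)
  graphics::points(pr$time[ev], pr$signal[ev], pch = 21, bg = "darkgreen")
  graphics::abline(h = x$psi, lty = 2, col = "blue")
  graphics::legend("topright", bty = "n",
                   legend = c("response", "signal", "threshold"),
                   pch = c(16, 21, NA), lty = c(1, NA, 2),
                   col = c("black", "black", "blue"),
                   pt.bg = c(NA, "darkgreen", NA))
  invisible(x)
}
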