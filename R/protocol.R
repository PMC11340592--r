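#' Stimulus protocols
#'
#' A stimulus protocol is an ordered sequence of events, each with a time, a
#' point in stimulus space, and a (log-scale) signal intensity. Signals are
#' taken as already log-transformed; the package applies no transduction.
#' Rows with `signal = NA` are probe points: response read-outs that
#' contribute no observation to the filter (e.g. single test trials after a
#' rest period).
#'
#' Protocols are stored as data frames with columns `time`, stimulus
#' coordinates `s1`...`sD`, and `signal`, carrying class
#' `"stimulus_protocol"`. Event times must be non-decreasing; duplicate
#' (time, stimulus) points are permitted (the observation-noise term keeps
#' the filter well-posed).
#'
#' @param time Numeric vector of event times (non-decreasing, finite).
#' @param signal Numeric vector of log-scale signal intensities (`NA` marks
#'   a probe point). Recycled to the length of `time`.
#' @param stimulus Stimulus-space coordinates: a single value or vector of
#'   length `D` (shared by all events), or a matrix with one row per event.
#'   Defaults to 0 (one-dimensional stimulus space).
#' @return A `stimulus_protocol` data frame.
#' @examples
#' stimulus_protocol(time = 0:4, signal = 0.2)
#' @seealso [stimulus_series()], [probe_events()], [concat_protocols()],
#'   [habituate()]
#' @export
stimulus_protocol <- function(time = numeric(), signal = numeric(), stimulus = 0) {
  n <- length(time)
  time <- as.double(time)
  signal <- rep_len(as.double(signal), if (n > 0L) n else length(signal))
  if (n == 0L) {
    out <- data.frame(time = numeric(), s1 = numeric(), signal = numeric())
    class(out) <- c("stimulus_protocol", "data.frame")
    return(out)
  }
  if (is.matrix(stimulus)) {
    if (nrow(stimulus) != n) {
      stop("invalid-protocol: stimulus matrix must have one row per event")
    }
    S <- stimulus
  } else {
    S <- matrix(rep(as.double(stimulus), each = n), nrow = n)
  }
  colnames(S) <- paste0("s", seq_len(ncol(S)))
  out <- data.frame(time = time, S, signal = signal)
  class(out) <- c("stimulus_protocol", "data.frame")
  validate_protocol(out)
}

#' @rdname stimulus_protocol
#' @param x Object to validate or test.
#' @export
validate_protocol <- function(x) {
  stopifnot(is.data.frame(x))
  scol <- grep("^s[0-9]+$", names(x), value = TRUE)
  if (!all(c("time", "signal") %in% names(x)) || length(scol) < 1L) {
    stop("invalid-protocol: need columns time, s1..sD, signal")
  }
  if (anyNA(x$time) || any(!is.finite(x$time))) {
    stop("invalid-protocol: event times must be finite")
  }
  if (is.unsorted(x$time)) {
    stop("invalid-protocol: event times must be non-decreasing")
  }
  if (any(!is.finite(as.matrix(x[, scol, drop = FALSE])))) {
    stop("invalid-protocol: stimulus coordinates must be finite")
  }
  if (any(!is.na(x$signal) & !is.finite(x$signal))) {
    stop("invalid-protocol: signals must be finite or NA (probe)")
  }
  x
}

#' @rdname stimulus_protocol
#' @export
is_probe <- function(x) is.na(x$signal)

#' Number of stimulus dimensions of a protocol
#' @param x A `stimulus_protocol`.
#' @return Integer `D >= 1`.
#' @export
stim_dim <- function(x) length(grep("^s[0-9]+$", names(x)))

#' @export
print.stimulus_protocol <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Stimulus protocol: %d rows (%d events, %d probes), D = %d\n",
              n, sum(!is_probe(x)), sum(is_probe(x)), stim_dim(x)))
  if (n > 0L) print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (n > 10L) cat("... (", n - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Build a repeated-stimulation series
#'
#' Events at arithmetic times `start_time + (0:(n_trials-1)) * interval`,
#' all with the same intensity and stimulus coordinates. Stimulation
#' frequency is the reciprocal of `interval`.
#'
#' @param n_trials Number of stimulus presentations (positive integer).
#' @param interval Inter-stimulus interval (positive).
#' @param intensity Log-scale signal value shared by all trials.
#' @param stimulus Stimulus-space coordinates (length-`D` vector).
#' @param start_time Time of the first trial.
#' @return A [stimulus_protocol()].
#' @examples
#' stimulus_series(10, interval = 0.1, intensity = 0.2)
#' @export
stimulus_series <- function(n_trials, interval, intensity,
                            stimulus = 0, start_time = 0) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1 ||
      n_trials != round(n_trials)) {
    stop("invalid-protocol: n_trials must be a positive integer")
  }
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0) {
    stop("invalid-protocol: interval must be positive")
  }
  stimulus_protocol(time = start_time + (seq_len(n_trials) - 1) * interval,
                    signal = intensity, stimulus = stimulus)
}

#' Probe points (response read-outs without an observation)
#'
#' @param time Times of the probes.
#' @param stimulus Stimulus coordinates of the probes.
#' @return A [stimulus_protocol()] of probe rows (`signal = NA`).
#' @export
probe_events <- function(time, stimulus = 0) {
  stimulus_protocol(time = time, signal = NA_real_, stimulus = stimulus)
}

#' Concatenate protocols with rest gaps
#'
#' Later blocks are shifted in time so that each block's first row occurs
#' `gap` time units after the previous block's last row; relative spacing
#' within each block is preserved. This realizes rest periods and
#' novel-stimulus insertions.
#'
#' @param ... `stimulus_protocol` objects (or a single list of them).
#' @param gap Non-negative rest(s) before each block after the first,
#'   recycled as needed.
#' @return A single time-ordered [stimulus_protocol()].
#' @examples
#' hab <- stimulus_series(10, 0.1, 0.2)
#' concat_protocols(hab, probe_events(0), gap = 1)  # recovery probe
#' @export
concat_protocols <- function(..., gap = 0) {
  blocks <- list(...)
  if (length(blocks) == 1L && !is.data.frame(blocks[[1L]])) blocks <- blocks[[1L]]
  if (length(blocks) == 0L) stop("invalid-protocol: no protocols to concatenate")
  blocks <- lapply(blocks, validate_protocol)
  D <- unique(vapply(blocks, stim_dim, integer(1)))
  if (length(D) != 1L) {
    stop("invalid-protocol: protocols have mismatched stimulus dimension")
  }
  gap <- rep_len(as.double(gap), max(1L, length(blocks) - 1L))
  if (any(gap < 0)) stop("invalid-protocol: gaps must be non-negative")
  out <- blocks[[1L]]
  for (i in seq_along(blocks)[-1L]) {
    b <- blocks[[i]]
    if (nrow(b) == 0L) next
    if (nrow(out) > 0L) {
      b$time <- b$time - b$time[1L] + out$time[nrow(out)] + gap[i - 1L]
    }
    out <- rbind(out, b)
  }
  class(out) <- c("stimulus_protocol", "data.frame")
  validate_protocol(out)
}

#' Common-test protocol
#'
#' A training series at one inter-stimulus interval followed by a block of
#' test trials whose successive spacings are a seeded random permutation of
#' `test_intervals`. Groups trained at different frequencies can then be
#' compared on an identical test block, separating learning from
#' performance effects.
#'
#' @param train_interval Inter-stimulus interval of the training series.
#' @param test_intervals Positive spacings to be permuted for the test block.
#' @param n_train Number of training trials.
#' @param intensity Log-scale signal value (shared by training and test).
#' @param stimulus Stimulus coordinates.
#' @param seed Integer seed for the permutation (the global RNG state is
#'   left untouched).
#' @return A [stimulus_protocol()].
#' @export
common_test_protocol <- function(train_interval, test_intervals, n_train = 10,
                                 intensity = 0.2, stimulus = 0, seed = 1) {
  if (length(test_intervals) < 1L || any(test_intervals <= 0)) {
    stop("invalid-protocol: test_intervals must be positive")
  }
  train <- stimulus_series(n_train, train_interval, intensity, stimulus)
  perm <- with_preserved_seed(seed, sample(length(test_intervals)))
  spacings <- test_intervals[perm]
  test_times <- train$time[nrow(train)] + cumsum(spacings)
  test <- stimulus_protocol(time = test_times, signal = intensity,
                            stimulus = stimulus)
  out <- rbind(train, test)
  class(out) <- c("stimulus_protocol", "data.frame")
  validate_protocol(out)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
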