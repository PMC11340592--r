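#' Run configurations: declarative protocols in YAML
#'
#' A run config is a YAML document with the blocks
#' \preformatted{
#' params:                      # optional, defaults shown
#'   alpha: 0.3
#'   psi: 0.5
#'   length_scale: 1.0
#'   condition_on_current: false
#' seed: 1                      # used by 'test' and 'generative' blocks
#' protocol:                    # ordered list of protocol blocks
#'   - series: {n_trials: 10, interval: 0.1, intensity: 0.2, stimulus: 0.0}
#'   - probe:  {delay: 0.5, stimulus: 0.0}
#'   - series: {n_trials: 10, interval: 0.1, intensity: 0.2, gap: 3.0}
#'   - test:   {intervals: [0.15, 0.2, 0.25], intensity: 0.2}
#'   - generative: {n_points: 20, interval: 0.2, stimulus: 0.0}
#' output:
#'   trace: trace.csv           # used by the command-line front end
#' }
#' Blocks are laid out sequentially: each block starts `gap` time units
#' after the previous block's last row (default: the block's own interval,
#' or `delay` for a probe). A `test` block appends events whose successive
#' spacings are a seeded permutation of `intervals`; a `generative` block
#' appends events whose signals are drawn from the model's own generative
#' process under the config seed. A run is reproducible from its config
#' alone.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: a list of class `"run_config"` with
#'   elements `params` (a [hab_params()]), `protocol` (the block list),
#'   `seed`, and `output`. `resolve_protocol()`: the assembled
#'   [stimulus_protocol()].
#' @name run_config
NULL

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname run_config
#' @param config A raw config list (as parsed from YAML).
#' @export
as_run_config <- function(config) {
  if (!is.list(config)) stop("config: top level must be a mapping")
  known <- c("params", "seed", "protocol", "output")
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("config: unknown key(s): ", paste(extra, collapse = ", "))
  p <- config$params
  if (is.null(p)) p <- list()
  pk <- setdiff(names(p), c("alpha", "psi", "length_scale", "condition_on_current"))
  if (length(pk)) stop("config: unknown key(s) under params: ",
                       paste(pk, collapse = ", "))
  params <- hab_params(
    alpha = p$alpha %||% 0.3, psi = p$psi %||% 0.5,
    length_scale = p$length_scale %||% 1,
    condition_on_current = isTRUE(p$condition_on_current))
  seed <- as.integer(config$seed %||% 1L)
  blocks <- config$protocol
  if (is.null(blocks) || length(blocks) == 0L) {
    stop("config: protocol must list at least one block")
  }
  for (i in seq_along(blocks)) .validate_block(blocks[[i]], i)
  structure(list(params = params, seed = seed, protocol = blocks,
                 output = config$output),
            class = "run_config")
}

.block_keys <- list(
  series = c("n_trials", "interval", "intensity", "stimulus", "gap"),
  probe = c("delay", "stimulus"),
  test = c("intervals", "intensity", "stimulus", "gap"),
  generative = c("n_points", "interval", "stimulus", "gap"))

.validate_block <- function(block, i) {
  if (!is.list(block) || length(block) != 1L || is.null(names(block))) {
    stop("config: protocol[", i, "] must be a single-key mapping ",
         "(series, probe, test or generative)")
  }
  kind <- names(block)
  if (!kind %in% names(.block_keys)) {
    stop("config: protocol[", i, "]: unknown block kind '", kind, "'")
  }
  extra <- setdiff(names(block[[1L]]), .block_keys[[kind]])
  if (length(extra)) {
    stop("config: protocol[", i, "].", kind, ": unknown key(s): ",
         paste(extra, collapse = ", "))
  }
  required <- switch(kind,
                     series = c("n_trials", "interval", "intensity"),
                     probe = "delay",
                     test = c("intervals", "intensity"),
                     generative = c("n_points", "interval"))
  missing <- setdiff(required, names(block[[1L]]))
  if (length(missing)) {
    stop("config: protocol[", i, "].", kind, ": missing key(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(block)
}

#' @rdname run_config
#' @export
resolve_protocol <- function(config) {
  stopifnot(inherits(config, "run_config"))
  blocks <- list()
  gaps <- numeric()
  for (i in seq_along(config$protocol)) {
    kind <- names(config$protocol[[i]])
    spec <- config$protocol[[i]][[1L]]
    stim <- spec$stimulus %||% 0
    built <- switch(kind,
      series = stimulus_series(spec$n_trials, spec$interval, spec$intensity,
                               stimulus = stim),
      probe = probe_events(0, stimulus = stim),
      test = {
        sp <- unlist(spec$intervals)
        perm <- with_preserved_seed(config$seed + i, sample(length(sp)))
        stimulus_protocol(time = cumsum(sp[perm]) - sp[perm][1L],
                          signal = spec$intensity, stimulus = stim)
      },
      generative = {
        g <- sample_gp_signals(times = (seq_len(spec$n_points) - 1) * spec$interval,
                               stimulus = stim,
                               alpha = config$params$alpha,
                               length_scale = config$params$length_scale,
                               seed = config$seed + i)
        g$history
      })
    gap <- spec$gap %||% switch(kind,
      series = spec$interval,
      probe = spec$delay,
      test = {
        sp <- unlist(spec$intervals)
        perm <- with_preserved_seed(config$seed + i, sample(length(sp)))
        sp[perm][1L]
      },
      generative = spec$interval)
    blocks <- c(blocks, list(built))
    if (i > 1L) gaps <- c(gaps, gap)
  }
  if (length(blocks) == 1L) blocks[[1L]] else concat_protocols(blocks, gap = gaps)
}

#' @rdname run_config
#' @param file Output YAML path.
#' @export
write_run_config <- function(config, file) {
  stopifnot(inherits(config, "run_config"))
  out <- list(params = list(alpha = config$params$alpha,
                            psi = config$params$psi,
                            length_scale = config$params$length_scale,
                            condition_on_current = config$params$condition_on_current),
              seed = config$seed,
              protocol = config$protocol)
  if (!is.null(config$output)) out$output <- config$output
  yaml::write_yaml(out, file)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
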