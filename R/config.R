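#' Default pipeline configuration
#'
#' Returns the nested list of parameters controlling every pipeline stage.
#' Unknown keys passed through `...` (or present in a YAML file loaded with
#' [read_config()]) are rejected, so typos cannot silently fall back to
#' defaults. All tunables are documented in the methods vignette.
#'
#' @param ... named overrides. Nested blocks are merged element-wise, e.g.
#'   `acusleep_config(enhancement = list(floor_db = -30))` changes one key
#'   and keeps the rest of the block.
#' @param seed integer seed from which every random component of the
#'   pipeline (simulation, detector and cascade training) derives its stream.
#' @return A named list with class `acusleep_config`.
#' @export
#' @examples
#' cfg <- acusleep_config(seed = 7, enhancement = list(oversubtraction = 2.5))
#' cfg$enhancement$oversubtraction
acusleep_config <- function(..., seed = 1L) {
  base <- list(
    seed = as.integer(seed),
    enhancement = list(
      window = 512L,         # centered Hann analysis window per 50 ms frame
      oversubtraction = 3,   # spectral over-subtraction factor
      floor_db = -25,        # spectral gain floor (amplitude dB)
      noise_quantile = 0.2,  # lowest-energy fraction of frames -> noise
      blend = 0.9,           # weight of previous profile when level falls
      blend_up = 0.7         # faster adaptation when the level rises
    ),
    detector = list(
      hidden = 16L,
      max_iter = 200L,
      learn_rate = 0.05,
      patience = 20L,
      l2 = 1e-4,
      val_frac = 0.2
    ),
    features = list(
      breath_threshold = 0.5, # min class probability inside a breath run
      min_run = 3L            # min frames (150 ms) for a detected event
    ),
    staging = list(
      # lookback windows and hidden-unit counts of the real-time cascade
      # (periods 2..6); period 1 is the constant-Wake rule
      rt_lookback = c(5L, 20L, 50L, 100L, 200L),
      rt_hidden = c(100L, 400L, 1000L, 1000L, 1000L),
      # lookahead windows and hidden-unit counts of the offline cascade
      off_lookahead = c(5L, 20L, 50L, 100L, 200L),
      off_hidden = c(20L, 50L, 100L, 200L, 200L),
      max_iter = 200L,
      learn_rate = 0.05,
      patience = 20L,
      l2 = 5e-4,
      dev_frac = 0.2,         # subject-level train/dev split
      allow_missing_periods = FALSE
    ),
    report = list(
      percent_denominator = "tst", # or "recording"
      rem_gap_epochs = 60L,        # REM runs closer than this merge (30 min)
      rem_min_epochs = 2L          # clusters smaller than this are dropped
    ),
    simulator = sim_config_defaults()
  )
  overrides <- list(...)
  if (length(overrides)) base <- merge_config(base, overrides, path = "config")
  structure(base, class = c("acusleep_config", "list"))
}

merge_config <- function(base, overrides, path) {
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    abort(sprintf("all overrides under '%s' must be named", path))
  }
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown)) {
    abort(sprintf(
      "unknown configuration key%s under '%s': %s",
      if (length(unknown) > 1) "s" else "", path,
      paste0(unknown, collapse = ", ")
    ))
  }
  for (key in names(overrides)) {
    if (is.list(base[[key]]) && is.list(overrides[[key]])) {
      base[[key]] <- merge_config(base[[key]], overrides[[key]],
                                  paste(path, key, sep = "$"))
    } else {
      base[[key]] <- overrides[[key]]
    }
  }
  base
}

#' Reduced-compute configuration profile
#'
#' The same pipeline with thinned cascade hidden layers, intended for
#' desk-scale experiments and the package's own test harness, where the
#' design corpus is tens of simulated nights rather than the hundreds of
#' patient-nights the full-width cascade is sized for. Window lengths,
#' period boundaries and all other defaults are unchanged.
#'
#' @inheritParams acusleep_config
#' @return An `acusleep_config` list.
#' @export
acusleep_config_reduced <- function(..., seed = 1L) {
  overrides <- list(...)
  thin <- list(rt_hidden = c(4L, 8L, 16L, 16L, 16L),
               off_hidden = c(4L, 8L, 10L, 16L, 16L))
  overrides$staging <- utils::modifyList(thin, overrides$staging %||% list())
  do.call(acusleep_config, c(overrides, list(seed = seed)))
}

#' Read a configuration file
#'
#' Loads a YAML file of overrides and merges it onto [acusleep_config()]
#' defaults, rejecting unknown keys.
#'
#' @param path path to a YAML file.
#' @return An `acusleep_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(acusleep_config, raw %||% list())
}

#' Hash of a configuration (or any R object)
#'
#' Stable content hash recorded in pipeline outputs so that results can be
#' traced back to the exact parameter set that produced them.
#'
#' @param x object to hash.
#' @return A character scalar.
#' @export
config_hash <- function(x) {
  unclass(rlang::hash(x))
}

#' @export
print.acusleep_config <- function(x, ...) {
  cat("<acusleep_config> seed =", x$seed, "hash =", config_hash(x), "\n")
  for (block in setdiff(names(x), "seed")) {
    vals <- x[[block]]
    if (is.list(vals)) {
      cat("  ", block, ": ", paste0(
        names(vals), "=",
        vapply(vals, function(v) paste0(format(v), collapse = "/"), ""),
        collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

# deterministic sub-seed derivation, kept below .Machine$integer.max
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
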