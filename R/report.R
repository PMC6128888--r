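#' Construct a hypnogram
#'
#' A per-epoch sequence of macro-sleep-stage labels (wake `W`, REM `R`,
#' NREM `N`) at the standard 30 s epoch resolution, epoch indices 1-based.
#'
#' @param labels character (or factor) vector of `"W"`, `"R"`, `"N"`.
#' @return A tibble with columns `epoch`, `stage`, class `hypnogram`.
#' @export
hypnogram <- function(labels) {
  labels <- as.character(labels)
  if (!length(labels)) abort("hypnogram must be non-empty")
  bad <- setdiff(unique(labels), STAGES)
  if (length(bad)) {
    abort(sprintf("invalid stage label(s): %s", paste(bad, collapse = ", ")))
  }
  new_tibble(list(epoch = seq_along(labels),
                  stage = factor(labels, levels = STAGES)),
             class = "hypnogram")
}

# coerce hypnogram / factor / character to a plain character vector
stage_vector <- function(h) {
  if (is.data.frame(h)) {
    if (!"stage" %in% names(h)) abort("hypnogram table needs a 'stage' column")
    return(as.character(h$stage))
  }
  as.character(hypnogram(h)$stage)
}

#' Eight-parameter sleep quality report
#'
#' Computes, from a hypnogram: total sleep time (`tst_min`, minutes scored
#' R or N), sleep latency (`sl_min`, start of recording to the first
#' non-wake epoch), sleep efficiency (`se_pct`, 100 * TST / recording
#' time), wake after sleep onset (`waso_min`, wake between sleep onset and
#' the final awakening), REM latency (`rl_min`, start of recording to the
#' first R epoch, `NA` when no REM occurred), REM and NREM percentages
#' (`rp_pct`, `np_pct`; of TST by default, of recording time with
#' `report$percent_denominator = "recording"`), and the REM-cycle count
#' (`rc_count`, see [count_rem_cycles()]).
#'
#' Identity: `sl_min + waso_min + tst_min +` terminal wake minutes equals
#' the recording length exactly whenever any sleep occurred.
#'
#' @param h a [hypnogram()] or character vector of stage labels.
#' @param config an [acusleep_config()]; the `report` block sets the
#'   percentage denominator and REM-cycle parameters.
#' @return A one-row tibble with the eight parameters, class `sleep_report`.
#' @export
#' @examples
#' h <- hypnogram(rep(c("W", "N", "R", "W"), c(10, 200, 50, 20)))
#' compute_report(h)
compute_report <- function(h, config = acusleep_config()) {
  s <- stage_vector(h)
  T <- length(s)
  total_min <- T / 2
  sleep <- s != "W"
  tst <- sum(sleep) / 2
  first_sleep <- if (any(sleep)) which(sleep)[1] else NA_integer_
  last_sleep <- if (any(sleep)) max(which(sleep)) else NA_integer_

  sl <- if (is.na(first_sleep)) NA_real_ else (first_sleep - 1) / 2
  waso <- if (is.na(first_sleep)) 0 else {
    sum(s[first_sleep:last_sleep] == "W") / 2
  }
  se <- 100 * tst / total_min
  first_rem <- if (any(s == "R")) which(s == "R")[1] else NA_integer_
  rl <- if (is.na(first_rem)) NA_real_ else (first_rem - 1) / 2

  denom <- switch(config$report$percent_denominator,
                  tst = tst, recording = total_min,
                  abort("report.percent_denominator must be 'tst' or 'recording'"))
  rp <- if (denom > 0) 100 * sum(s == "R") / 2 / denom else NA_real_
  np <- if (denom > 0) 100 * sum(s == "N") / 2 / denom else NA_real_

  new_tibble(list(
    tst_min = tst, sl_min = sl, se_pct = se, waso_min = waso,
    rl_min = rl, rp_pct = rp, np_pct = np,
    rc_count = count_rem_cycles(s, config)
  ), class = "sleep_report")
}

#' Count REM cycles
#'
#' Maximal runs of REM epochs are merged into one cycle when separated by
#' fewer than `report$rem_gap_epochs` non-REM epochs (default 60 epochs =
#' 30 min); merged clusters containing fewer than `report$rem_min_epochs`
#' REM epochs (default 2, i.e. 1 min) are discarded as scoring noise.
#'
#' @inheritParams compute_report
#' @return Integer cycle count.
#' @export
count_rem_cycles <- function(h, config = acusleep_config()) {
  s <- stage_vector(h)
  gap <- config$report$rem_gap_epochs
  min_ep <- config$report$rem_min_epochs
  r <- rle(s == "R")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values],
                 n = r$lengths[r$values])
  if (!nrow(runs)) return(0L)
  cluster <- cumsum(c(1L, as.integer(
    runs$start[-1] - runs$end[-nrow(runs)] - 1L >= gap
  )))
  sizes <- tapply(runs$n, cluster, sum)
  sum(sizes >= min_ep)
}

#' @export
print.sleep_report <- function(x, ...) {
  cat("Sleep quality report\n")
  cat(sprintf("  TST  %6.1f min   SL   %6.1f min   SE   %5.1f %%\n",
              x$tst_min, x$sl_min, x$se_pct))
  cat(sprintf("  WASO %6.1f min   RL   %6s min   RC   %d cycles\n",
              x$waso_min,
              ifelse(is.na(x$rl_min), "NA", sprintf("%.1f", x$rl_min)),
              x$rc_count))
  cat(sprintf("  REM  %5.1f %%     NREM %5.1f %%\n", x$rp_pct, x$np_pct))
  invisible(x)
}

#' Write a sleep report
#'
#' Emits the report as JSON (units embedded in the field names) or as a
#' one-row CSV.
#'
#' @param report a `sleep_report`.
#' @param path output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
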