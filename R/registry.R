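# The frozen, versioned 67-feature registry: five families with sizes
# 33 / 12 / 10 / 8 / 4. Downstream models record the registry hash so a
# cascade can never be applied to features laid out differently.

REGISTRY_VERSION <- "1"

registry_names <- list(
  within_breathing = c(
    "in_count", "ex_count",
    "in_dur_mean", "in_dur_sd", "in_dur_max",
    "ex_dur_mean", "ex_dur_sd", "ex_dur_max",
    "in_int_mean", "in_int_sd", "ex_int_mean", "ex_int_sd",
    "in_ex_int_ratio",
    "br_centroid_mean", "br_centroid_sd",
    "br_entropy_mean", "br_entropy_sd",
    "br_rolloff_mean", "br_rolloff_sd",
    paste0("br_band", 1:4, "_mean"),
    "br_zcr_mean", "br_zcr_sd",
    paste0("br_cep", 1:6, "_mean"),
    "br_harmonic_frac", "breath_duty_cycle"
  ),
  between_breathing = c(
    "ibi_mean", "ibi_sd", "ibi_cv",
    "acf_peak_height", "acf_peak_lag",
    "dom_breath_freq", "dom_breath_mag",
    "regularity_ratio", "duty_cycle_var",
    "in_ex_interval_mean", "in_ex_interval_sd",
    "breath_detect_frac"
  ),
  body_movement = c(
    "bm_count", "bm_frac", "bm_dur_mean", "bm_dur_max",
    "bm_int_mean", "bm_int_max", "bm_frames_since_last",
    "bm_p_mean", "bm_free_run_max", "bm_half_diff"
  ),
  background_noise = c(
    "os_count", "os_frac", "os_int_mean", "os_int_max",
    "noise_floor_db", "noise_floor_delta",
    "os_centroid_mean", "transient_rate"
  ),
  personalization = c("age", "gender", "bmi", "epoch_index")
)

#' The epoch feature registry
#'
#' The fixed, versioned order of the 67 epoch features: five families of
#' sizes 33 (within-breathing), 12 (between-breathing), 10 (body movement),
#' 8 (background noise) and 4 (personalization). The index/name mapping is
#' bijective; every feature matrix and trained cascade records this
#' registry's hash.
#'
#' @return A tibble with `index`, `name`, `family`.
#' @export
feature_registry <- function() {
  tibble(
    index = seq_along(unlist(registry_names)),
    name = unname(unlist(registry_names)),
    family = rep(names(registry_names),
                 vapply(registry_names, length, integer(1)))
  )
}

registry_hash <- function() {
  config_hash(list(REGISTRY_VERSION, registry_names))
}

#' Write a per-night feature matrix with its registry manifest
#'
#' Writes the epoch-by-feature table as CSV (rows = epochs, columns =
#' registry names) together with a sidecar JSON manifest recording the
#' registry version, hash, and family layout, so the file can be
#' validated before re-use.
#'
#' @param features a feature table from [extract_night_features()].
#' @param path output CSV path; the manifest is written next to it with
#'   a `.registry.json` suffix.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  manifest <- list(
    registry_version = REGISTRY_VERSION,
    registry_hash = registry_hash(),
    families = lapply(registry_names, as.list),
    n_epochs = nrow(features)
  )
  jsonlite::write_json(manifest,
                       paste0(sub("\\.csv$", "", path), ".registry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
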