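#' Build a neonatal-style atlas label table
#'
#' Constructs the label table that defines network nodes: `n_per_hemisphere`
#' regions per side (64 labels in total by default, mirroring the size of the
#' JHU neonate parcellation), homotopic left/right pairing, and one
#' fronto-limbic region-of-interest flag per hemisphere for each of the four
#' circuit members: medial fronto-orbital gyrus (`mfog`), superior temporal
#' gyrus (`stg`), `amygdala`, and `hippocampus`.
#'
#' Label identifiers are integers: left-hemisphere labels come first
#' (`1..n_per_hemisphere`), then right-hemisphere labels. Homotopic partners
#' share a `pair_id`. Region names are synthetic placeholders except for the
#' four flagged fronto-limbic regions.
#'
#' @param n_per_hemisphere Number of regions per hemisphere (default 32).
#' @return A tibble with columns `label_id` (integer), `name` (character),
#'   `hemisphere` (`"left"`/`"right"`), `pair_id` (integer), and `roi_flag`
#'   (`"none"`, `"mfog"`, `"stg"`, `"amygdala"`, or `"hippocampus"`).
#' @examples
#' atlas <- neonatal_atlas()
#' dplyr::count(atlas, hemisphere)
#' @export
neonatal_atlas <- function(n_per_hemisphere = 32L) {
  n_per_hemisphere <- as.integer(n_per_hemisphere)
  if (is.na(n_per_hemisphere) || n_per_hemisphere < 4L) {
    abort("`n_per_hemisphere` must be an integer >= 4.", class = "hemilat_config_error")
  }
  rois <- c("mfog", "stg", "amygdala", "hippocampus")
  roi_flag <- rep("none", n_per_hemisphere)
  roi_flag[seq_along(rois)] <- rois
  base_name <- ifelse(roi_flag == "none",
                      sprintf("region_%02d", seq_len(n_per_hemisphere)),
                      roi_flag)
  tibble(
    label_id   = c(seq_len(n_per_hemisphere),
                   n_per_hemisphere + seq_len(n_per_hemisphere)),
    name       = c(paste0("L_", base_name), paste0("R_", base_name)),
    hemisphere = rep(c("left", "right"), each = n_per_hemisphere),
    pair_id    = rep(seq_len(n_per_hemisphere), 2L),
    roi_flag   = rep(roi_flag, 2L)
  )
}

validate_atlas <- function(atlas) {
  req <- c("label_id", "name", "hemisphere", "pair_id", "roi_flag")
  missing_cols <- setdiff(req, names(atlas))
  if (length(missing_cols) > 0) {
    abort(paste0("Atlas table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "hemilat_input_error")
  }
  if (anyDuplicated(atlas$label_id)) {
    abort("Atlas label_id values must be unique.", class = "hemilat_input_error")
  }
  bad_hemi <- setdiff(unique(atlas$hemisphere), c("left", "right", "midline"))
  if (length(bad_hemi) > 0) {
    abort(paste0("Unknown hemisphere value(s): ", paste(bad_hemi, collapse = ", ")),
          class = "hemilat_input_error")
  }
  paired <- atlas[atlas$hemisphere %in% c("left", "right") & !is.na(atlas$pair_id), ]
  tab <- table(paired$pair_id, paired$hemisphere)
  if (nrow(tab) > 0 && any(tab > 1)) {
    abort("Each pair_id may appear at most once per hemisphere.",
          class = "hemilat_input_error")
  }
  invisible(atlas)
}

atlas_side_labels <- function(atlas, side) {
  atlas$label_id[atlas$hemisphere == side]
}
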