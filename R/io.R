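# Delimited-text readers and writers. All files are UTF-8 TSV with '.' as
# the decimal separator and '#'-prefixed metadata lines; writers and readers
# round-trip bit-exactly on the package's own output.

hemilat_header <- function(seed = NULL) {
  c(sprintf("# hemilat %s", as.character(utils::packageVersion("hemilat"))),
    if (!is.null(seed)) sprintf("# seed=%s", format(seed)))
}

write_tsv_with_header <- function(df, path, seed = NULL) {
  writeLines(hemilat_header(seed), path)
  vroom_safe <- readr::format_tsv(df)
  cat(vroom_safe, file = path, append = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = col_types, progress = FALSE)
}

#' Read and write atlas label tables
#'
#' Schema: `label_id`, `name`, `hemisphere`, `pair_id`, `roi_flag`.
#'
#' @param path File path.
#' @param atlas Atlas tibble, see [neonatal_atlas()].
#' @param seed Optional seed recorded in the file header.
#' @return `read_atlas()` returns the validated atlas tibble;
#'   `write_atlas()` returns `path` invisibly.
#' @export
read_atlas <- function(path) {
  atlas <- read_tsv_plain(path, readr::cols(
    label_id = readr::col_integer(), name = readr::col_character(),
    hemisphere = readr::col_character(), pair_id = readr::col_integer(),
    roi_flag = readr::col_character()))
  validate_atlas(atlas)
  atlas
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, path, seed = NULL) {
  validate_atlas(atlas)
  write_tsv_with_header(atlas, path, seed)
}

#' Read and write cohort covariate tables
#'
#' @param path File path.
#' @param cohort Cohort tibble, see [simulate_cohort_table()].
#' @param seed Optional seed recorded in the file header.
#' @return `read_cohort_table()` returns the cohort tibble.
#' @export
read_cohort_table <- function(path) {
  tab <- read_tsv_plain(path)
  req <- c("subject_id", "group")
  if (!all(req %in% names(tab))) {
    abort("Cohort table must have subject_id and group columns.",
          class = "hemilat_input_error")
  }
  tab
}

#' @rdname read_cohort_table
#' @export
write_cohort_table <- function(cohort, path, seed = NULL) {
  write_tsv_with_header(cohort, path, seed)
}

#' Read and write square connectivity matrices
#'
#' The file is a square TSV with a leading `label_id` column and one column
#' per label; the matrix must be symmetric with zero diagonal.
#'
#' @param path File path.
#' @param mat Numeric matrix with label dimnames.
#' @param seed Optional seed recorded in the file header.
#' @return `read_matrix_tsv()` returns a numeric matrix with label dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_plain(path)
  labs <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  header_labs <- suppressWarnings(as.integer(colnames(m)))
  if (anyNA(header_labs) || !identical(as.integer(labs), header_labs)) {
    abort("Matrix row labels do not match the header labels.",
          class = "hemilat_input_error")
  }
  dimnames(m) <- list(labs, labs)
  if (!isTRUE(all.equal(m, t(m)))) {
    abort("Matrix file is not symmetric.", class = "hemilat_input_error")
  }
  if (any(diag(m) != 0)) {
    abort("Matrix diagonal must be zero.", class = "hemilat_input_error")
  }
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(mat, path, seed = NULL) {
  df <- tibble(label_id = as.integer(rownames(mat)))
  df <- dplyr::bind_cols(df, as_tibble(mat, .name_repair = "minimal"))
  write_tsv_with_header(df, path, seed)
}

#' Read and write streamline summary tables
#'
#' Schema: `subject_id`, `label_a`, `label_b`, `fiber`, and `voxel_fa` as a
#' comma-joined list of per-voxel FA values.
#'
#' @param path File path.
#' @param streamlines Streamline tibble with a `voxel_fa` list-column.
#' @param seed Optional seed recorded in the file header.
#' @return `read_streamlines()` returns the streamline tibble with
#'   `voxel_fa` restored as a list-column.
#' @export
read_streamlines <- function(path) {
  df <- read_tsv_plain(path, readr::cols(
    subject_id = readr::col_character(), label_a = readr::col_integer(),
    label_b = readr::col_integer(), fiber = readr::col_integer(),
    voxel_fa = readr::col_character()))
  df$voxel_fa <- lapply(strsplit(df$voxel_fa, ","), as.numeric)
  df
}

#' @rdname read_streamlines
#' @export
write_streamlines <- function(streamlines, path, seed = NULL) {
  flat <- streamlines
  flat$voxel_fa <- vapply(
    streamlines$voxel_fa,
    function(v) paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                      collapse = ","),
    character(1))
  write_tsv_with_header(flat, path, seed)
}

#' Write every pipeline output table of a results bundle
#'
#' Writes `metrics.tsv`, `asymmetry.tsv`, `comparison.tsv`,
#' `age_correlation.tsv` and, when present, `subgroup.tsv` into `dir`, each
#' with the package-version/seed header.
#'
#' @param results A `hemilat_results` object from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    write_tsv_with_header(as_tibble(unclass(df)), file.path(dir, name),
                          seed = results$seed)
  }
  w(results$metrics, "metrics.tsv")
  w(results$asymmetry, "asymmetry.tsv")
  w(results$comparison, "comparison.tsv")
  w(results$age_correlation, "age_correlation.tsv")
  if (!is.null(results$subgroup)) w(results$subgroup, "subgroup.tsv")
  invisible(dir)
}

#' Write a synthetic cohort to disk
#'
#' Cohort table as TSV, each subject's binary and FA matrices as
#' `{subject_id}_{view}.tsv`, and the generator configuration as a JSON
#' sidecar.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cohort_table(cohort$cohort_table, file.path(dir, "cohort.tsv"),
                     seed = cohort$seed)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"), seed = cohort$seed)
  for (id in names(cohort$connectomes)) {
    conn <- cohort$connectomes[[id]]
    write_matrix_tsv(conn$binary, file.path(dir, paste0(id, "_binary.tsv")),
                     seed = cohort$seed)
    write_matrix_tsv(conn$fa_weight, file.path(dir, paste0(id, "_fa.tsv")),
                     seed = cohort$seed)
  }
  cfg <- unclass(cohort$config)
  cfg$covariates <- NULL  # nested defaults; regenerate via sim_config()
  cfg$roi_extra_edges <- as.list(cfg$roi_extra_edges)
  jsonlite::write_json(
    list(seed = cohort$seed, config = cfg),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
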