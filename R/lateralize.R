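#' Hemispheric asymmetry score
#'
#' `AS = 100 * (X(L) - X(R)) / (X(L) + X(R))` for a nonnegative network
#' measure `X` evaluated in each hemisphere. The score is bounded in
#' `[-100, 100]`, scale-invariant, and antisymmetric under hemisphere swap.
#' Positive values indicate leftward dominance of the measure. For measures
#' where larger is "worse" (characteristic path length), the sign is reported
#' as-is and interpretation is left to the analyst.
#'
#' @param x_left,x_right Nonnegative metric values (vectorized).
#' @return The asymmetry score(s); `NA_real_` where `x_left + x_right == 0`
#'   (undefined asymmetry, excluded downstream rather than raising an error).
#' @examples
#' asymmetry_score(1.219, 1.179)  # leftward, +1.67
#' @export
asymmetry_score <- function(x_left, x_right) {
  if (any(x_left < 0, na.rm = TRUE) || any(x_right < 0, na.rm = TRUE)) {
    abort("Asymmetry scores are defined for nonnegative metric values.",
          class = "hemilat_input_error")
  }
  s <- x_left + x_right
  out <- ifelse(s > 0, 100 * (x_left - x_right) / s, NA_real_)
  as.numeric(out)
}

#' Per-subject asymmetry records for a cohort
#'
#' Pairs each subject's left and right values of every metric and computes
#' the asymmetry score. Input is the long metric table produced by
#' [cohort_metrics()] (columns `subject_id`, `hemisphere`, `metric`,
#' `value`).
#'
#' @param metrics Long tibble of per-subject, per-hemisphere metric values.
#' @return A tibble with `subject_id`, `metric`, `x_left`, `x_right`, `as`,
#'   and `defined` (FALSE where the score is undefined). Undefined records
#'   are counted in a message.
#' @export
lateralize_cohort <- function(metrics) {
  req <- c("subject_id", "hemisphere", "metric", "value")
  if (!all(req %in% names(metrics))) {
    abort(paste0("`metrics` must have columns: ", paste(req, collapse = ", ")),
          class = "hemilat_input_error")
  }
  metrics <- metrics[metrics$hemisphere %in% c("left", "right"), req]
  # structural missingness (a subject with no rows at all for one side) is an
  # input error; an NA metric value only makes that record undefined
  sides <- unique(metrics[, c("subject_id", "hemisphere")])
  per_subj <- table(sides$subject_id)
  one_sided <- names(per_subj)[per_subj < 2]
  if (length(one_sided) > 0) {
    abort(paste0("Subject(s) present in only one hemisphere: ",
                 paste(head(one_sided, 5), collapse = ", ")),
          class = "hemilat_input_error")
  }
  wide <- tidyr::pivot_wider(metrics, names_from = "hemisphere",
                             values_from = "value")
  out <- tibble(
    subject_id = wide$subject_id,
    metric = wide$metric,
    x_left = wide$left,
    x_right = wide$right,
    as = asymmetry_score(wide$left, wide$right)
  )
  out$defined <- !is.na(out$as)
  n_undef <- sum(!out$defined)
  if (n_undef > 0) {
    inform(sprintf("lateralize_cohort: %d undefined asymmetry record(s).",
                   n_undef))
  }
  out
}
# NA x_left/x_right (e.g. small-worldness undefined on a triangle-free
# hemisphere) propagates to an undefined record rather than an error.
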