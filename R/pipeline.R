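# End-to-end orchestration: connectomes -> hemispheric networks -> metrics
# -> asymmetry scores -> covariate-adjusted FDR-controlled comparisons.

metric_keys <- function() {
  c("lp", "eglob", "cp", "elocal", "sigma",
    "bc_mfog", "bc_stg", "bc_amygdala", "bc_hippocampus")
}

#' Per-subject hemispheric metrics for a whole cohort
#'
#' Splits every connectome into left/right intra-hemispheric binary networks
#' and computes the five global measures plus the four fronto-limbic
#' betweenness values per hemisphere. Each subject's small-worldness null
#' ensemble uses its own seed derived from `seed` by the package's counter
#' scheme, so results are reproducible subject by subject.
#'
#' @param connectomes Named list of `connectome` objects (names are subject
#'   ids).
#' @param atlas Atlas label table.
#' @param n_random Random references per small-worldness evaluation.
#' @param seed Master integer seed for the null ensembles.
#' @param orientation Small-worldness orientation, see [small_worldness()].
#' @return A long tibble: `subject_id`, `hemisphere`, `metric`, `value`.
#' @export
cohort_metrics <- function(connectomes, atlas, n_random = 100, seed = 1L,
                           orientation = c("standard", "printed")) {
  orientation <- match.arg(orientation)
  validate_atlas(atlas)
  rois <- c("mfog", "stg", "amygdala", "hippocampus")
  keys <- metric_keys()
  vals <- lapply(seq_along(connectomes), function(i) {
    conn <- connectomes[[i]]
    halves <- split_hemispheres(conn, atlas, quiet = TRUE)
    unlist(lapply(halves, function(net) {
      sw <- suppressWarnings(small_worldness(
        net, n_random = n_random, seed = subject_seed(seed, 500000 + i),
        orientation = orientation))
      A <- net$adjacency
      btw <- betweenness_centrality(net)
      roi_labs <- vapply(rois, function(r) {
        lab <- atlas$label_id[atlas$roi_flag == r & atlas$hemisphere == net$side]
        if (length(lab) != 1 || !(lab %in% net$labels)) {
          abort(sprintf("ROI '%s' not found in the %s hemisphere's node set.",
                        r, net$side), class = "hemilat_input_error")
        }
        lab
      }, integer(1))
      c(lp_from_dist(adj_dist(A)), eglob_from_dist(adj_dist(A)),
        mean(adj_clustering(A)), mean(adj_local_eff(A)), sw$sigma,
        unname(btw[match(roi_labs, net$labels)]))
    }), use.names = FALSE)
  })
  n_sub <- length(connectomes)
  tibble(
    subject_id = rep(vapply(connectomes, function(x) x$subject_id,
                            character(1)), each = 2L * length(keys)),
    hemisphere = rep(rep(c("left", "right"), each = length(keys)), n_sub),
    metric = rep(keys, 2L * n_sub),
    value = unlist(vals, use.names = FALSE)
  )
}

#' Run the full lateralization pipeline
#'
#' Executes metric computation, asymmetry scoring, the covariate-adjusted
#' group comparison of asymmetry scores (with BH correction within the global
#' and fronto-limbic families), the age-at-MRI correlation screen, and --
#' when the cohort supports it -- the Bayley-SE subgroup comparison among
#' assessed preterm subjects.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()], or a list
#'   with elements `cohort_table`, `connectomes`, `atlas`.
#' @param n_random Random references per small-worldness evaluation.
#' @param seed Master seed for the null ensembles.
#' @param orientation Small-worldness orientation.
#' @param covariates Covariates for the group comparison.
#' @param subgroup Run the Bayley-SE subgroup analysis if feasible.
#' @param alpha Significance level for FDR-adjusted p-values.
#' @return A `hemilat_results` list: `metrics`, `asymmetry`, `comparison`,
#'   `age_correlation`, `subgroup`, `seed`, `n_random`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_preterm = 6, n_term = 5), seed = 1)
#' res <- run_pipeline(cohort, n_random = 5, seed = 1)
#' res$comparison
#' }
#' @export
run_pipeline <- function(cohort, n_random = 100, seed = 1L,
                         orientation = c("standard", "printed"),
                         covariates = c("sex", "age_at_mri", "bpd"),
                         subgroup = TRUE, alpha = 0.05) {
  orientation <- match.arg(orientation)
  needed <- c("cohort_table", "connectomes", "atlas")
  if (!all(needed %in% names(cohort))) {
    abort("`cohort` must contain cohort_table, connectomes, and atlas.",
          class = "hemilat_input_error")
  }
  missing_conn <- setdiff(cohort$cohort_table$subject_id,
                          names(cohort$connectomes))
  if (length(missing_conn) > 0) {
    abort(paste0("Missing connectome(s) for subject(s): ",
                 paste(head(missing_conn, 5), collapse = ", ")),
          class = "hemilat_input_error")
  }
  metrics <- cohort_metrics(cohort$connectomes, cohort$atlas,
                            n_random = n_random, seed = seed,
                            orientation = orientation)
  asymmetry <- lateralize_cohort(metrics)
  comparison <- compare_lateralization(asymmetry, cohort$cohort_table,
                                       covariates = covariates, alpha = alpha)
  age_corr <- correlate_with_age(asymmetry, cohort$cohort_table)
  sub_res <- NULL
  if (isTRUE(subgroup)) {
    tab <- cohort$cohort_table
    feasible <- "se_subgroup" %in% names(tab) &&
      sum(tab$group == "preterm" & tab$assessed &
            tab$se_subgroup %in% "abnormal") >= 2 &&
      sum(tab$group == "preterm" & tab$assessed &
            tab$se_subgroup %in% "normal") >= 2
    if (feasible) {
      sub_res <- subgroup_compare(asymmetry, tab, alpha = alpha)
    }
  }
  structure(
    list(metrics = metrics, asymmetry = asymmetry, comparison = comparison,
         age_correlation = age_corr, subgroup = sub_res,
         seed = seed, n_random = n_random, orientation = orientation),
    class = "hemilat_results"
  )
}

#' @export
print.hemilat_results <- function(x, ...) {
  cat(sprintf("<hemilat_results> %d subjects, %d metrics, seed %s\n",
              length(unique(x$metrics$subject_id)),
              length(unique(x$metrics$metric)), format(x$seed)))
  sig <- x$comparison$metric[x$comparison$significant]
  cat(" FDR-significant asymmetry differences:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Replicate-cohort calibration study
#'
#' Simulates `n_reps` independent cohorts under one configuration, runs the
#' pipeline on each, and records whether any global-family asymmetry
#' comparison is FDR-significant, whether the small-worldness asymmetry
#' specifically is, and the realized standardized group difference of the
#' small-worldness asymmetry score (pooled-SD units). With a null
#' configuration this estimates the family false-positive rate; with a
#' planted effect it estimates detection power.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicate cohorts.
#' @param seed Master seed; replicate r uses a derived seed.
#' @param n_random Random references per small-worldness evaluation.
#' @param covariates Covariates for the group comparison.
#' @return A tibble with one row per replicate: `rep`, `any_global_sig`,
#'   `sigma_sig`, `sigma_d` plus attribute `"summary"` (rates and mean d).
#' @export
replicate_study <- function(config, n_reps = 100, seed = 1L, n_random = 10,
                            covariates = c("sex", "age_at_mri", "bpd")) {
  rows <- lapply(seq_len(n_reps), function(r) {
    rep_seed <- subject_seed(seed, 900000 + r * 17)
    cohort <- simulate_cohort(config, seed = rep_seed)
    res <- suppressMessages(run_pipeline(
      cohort, n_random = n_random, seed = rep_seed,
      covariates = covariates, subgroup = FALSE))
    comp <- res$comparison
    glob <- comp[comp$family == "global", ]
    sig_asym <- res$asymmetry[res$asymmetry$metric == "sigma" &
                                res$asymmetry$defined, ]
    d <- standardized_group_diff(sig_asym, cohort$cohort_table)
    tibble(
      rep = r,
      any_global_sig = any(glob$significant),
      sigma_sig = comp$significant[comp$metric == "sigma"],
      sigma_d = d
    )
  })
  out <- bind_rows(rows)
  attr(out, "summary") <- list(
    family_sig_rate = mean(out$any_global_sig),
    sigma_detection_rate = mean(out$sigma_sig),
    mean_sigma_d = mean(out$sigma_d, na.rm = TRUE)
  )
  out
}

# Standardized preterm-minus-term difference of an asymmetry score, in
# pooled within-group SD units.
standardized_group_diff <- function(asym_one_metric, cohort_table) {
  d <- dplyr::left_join(asym_one_metric[, c("subject_id", "as")],
                        cohort_table[, c("subject_id", "group")],
                        by = "subject_id")
  a <- d$as[d$group == "preterm"]; b <- d$as[d$group == "term"]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}
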