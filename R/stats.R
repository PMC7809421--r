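# Statistical stage: cohort-table tests, covariate-adjusted comparison of
# asymmetry scores, BH false-discovery-rate control within figure-style
# outcome families, age correlation, Bayley-SE subgrouping, and the
# two-proportion sample-size formula.

check_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x))) {
    abort("Cell counts must be nonnegative integers.",
          class = "hemilat_input_error")
  }
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Contingency table has an empty margin.",
          class = "hemilat_input_error")
  }
  m
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric point probabilities no larger
#' than that of the observed table. Cells are given row-wise:
#' `a, b` (first row), `c, d` (second row).
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(13, 44, 0, 21)  # ~0.017
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  m <- check_2x2(a, b, c, d)
  unname(fisher.test(m, alternative = "two.sided")$p.value)
}

#' Chi-square test for a 2x2 table
#'
#' @inheritParams fisher_exact_2x2
#' @param yates Apply Yates' continuity correction.
#' @return A list with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d, yates = FALSE) {
  m <- check_2x2(a, b, c, d)
  res <- suppressWarnings(chisq.test(m, correct = yates))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Two-group comparison of a continuous variable
#'
#' Student's (pooled-variance) t-test or the Mann-Whitney U-test, two-sided.
#' The Mann-Whitney path uses exact enumeration for small untied samples
#' (total n <= 20) and the tie-corrected normal approximation otherwise,
#' with midranks for ties.
#'
#' @param values Numeric outcome vector.
#' @param group Two-level grouping vector aligned with `values`.
#' @param method `"student_t"` or `"mann_whitney"`.
#' @return The two-sided p-value.
#' @export
group_test <- function(values, group, method = c("student_t", "mann_whitney")) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- as.factor(as.character(group[keep]))
  if (nlevels(group) != 2 || any(table(group) < 2)) {
    abort("`group` must have two levels with >= 2 observations each.",
          class = "hemilat_input_error")
  }
  x <- values[group == levels(group)[1]]
  y <- values[group == levels(group)[2]]
  if (method == "student_t") {
    t.test(x, y, var.equal = TRUE)$p.value
  } else {
    exact <- length(values) <= 20 && !anyDuplicated(values)
    suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, as implemented by
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_bh <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1].", class = "hemilat_input_error")
  }
  p.adjust(p, method = "BH")
}

#' Covariate-adjusted two-group comparison by ordinary least squares
#'
#' Regresses the outcome on a two-level group indicator plus covariates; the
#' reported effect is the group coefficient (second factor level minus the
#' first) with its two-sided t-test p-value. This is the general-linear-model
#' comparison used for network measures and asymmetry scores.
#'
#' @param data A data frame holding outcome, group, and covariate columns.
#' @param outcome Name of the outcome column.
#' @param group_var Name of the two-level group column.
#' @param covariates Character vector of covariate column names (may be
#'   empty, in which case the comparison reduces to a pooled t-test).
#' @return A one-row tibble: `outcome`, `effect`, `se`, `p_raw`, `n1`, `n2`,
#'   `group_levels`.
#' @export
glm_adjusted_compare <- function(data, outcome, group_var = "group",
                                 covariates = character()) {
  cols <- c(outcome, group_var, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "hemilat_input_error")
  }
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  d[[group_var]] <- factor(as.character(d[[group_var]]))
  if (nlevels(d[[group_var]]) != 2) {
    abort("Group variable must have exactly two observed levels.",
          class = "hemilat_input_error")
  }
  rhs <- paste(c(group_var, covariates), collapse = " + ")
  fit <- lm(stats::as.formula(paste0("`", outcome, "` ~ ", rhs)), data = d)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(paste0("Rank-deficient design; collinear term(s): ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")),
          class = "hemilat_input_error")
  }
  sm <- summary(fit)$coefficients
  grp_row <- grep(paste0("^", group_var), rownames(sm))[1]
  lv <- levels(d[[group_var]])
  tibble(
    outcome = outcome,
    effect = sm[grp_row, "Estimate"],
    se = sm[grp_row, "Std. Error"],
    p_raw = sm[grp_row, "Pr(>|t|)"],
    n1 = sum(d[[group_var]] == lv[1]),
    n2 = sum(d[[group_var]] == lv[2]),
    group_levels = paste(lv[2], "minus", lv[1])
  )
}

metric_family <- function(metric) {
  ifelse(startsWith(metric, "bc_"), "roi_betweenness", "global")
}

#' Compare asymmetry scores between groups with covariate adjustment and FDR
#'
#' For every metric in the asymmetry table, fits the covariate-adjusted
#' linear model of [glm_adjusted_compare()] for group differences in the
#' asymmetry score, then applies Benjamini-Hochberg correction within outcome
#' families: the global network measures form one family and the fronto-limbic
#' betweenness scores (`bc_*`) another, mirroring how such comparisons are
#' reported figure by figure. Undefined asymmetry records are dropped
#' per-metric with a message.
#'
#' @param asymmetry Tibble from [lateralize_cohort()].
#' @param cohort Cohort covariate table with `subject_id`, the group column
#'   and the covariates.
#' @param group_var Two-level group column name (default `"group"`).
#' @param covariates Covariate column names; default
#'   `c("sex", "age_at_mri", "bpd")`.
#' @param alpha Significance level applied to FDR-adjusted p-values.
#' @return A `hemilat_comparison` tibble: `metric`, `family`, `effect`, `se`,
#'   `p_raw`, `p_fdr`, `significant`, `n1`, `n2`, `group_levels`.
#' @export
compare_lateralization <- function(asymmetry, cohort, group_var = "group",
                                   covariates = c("sex", "age_at_mri", "bpd"),
                                   alpha = 0.05) {
  n_undef <- sum(!asymmetry$defined)
  if (n_undef > 0) {
    inform(sprintf(
      "compare_lateralization: dropping %d undefined asymmetry record(s).",
      n_undef))
  }
  asym <- asymmetry[asymmetry$defined, ]
  metrics <- unique(asym$metric)
  rows <- lapply(metrics, function(m) {
    d <- dplyr::left_join(asym[asym$metric == m, c("subject_id", "as")],
                          cohort, by = "subject_id")
    res <- glm_adjusted_compare(d, "as", group_var, covariates)
    res$outcome <- NULL
    tibble(metric = m, family = metric_family(m), res)
  })
  out <- bind_rows(rows)
  out <- out |>
    group_by(.data$family) |>
    mutate(p_fdr = fdr_bh(.data$p_raw)) |>
    ungroup() |>
    mutate(significant = .data$p_fdr < alpha) |>
    select("metric", "family", "effect", "se", "p_raw", "p_fdr",
           "significant", "n1", "n2", "group_levels")
  attr(out, "covariates") <- covariates
  attr(out, "alpha") <- alpha
  class(out) <- c("hemilat_comparison", class(out))
  out
}

#' @export
tidy.hemilat_comparison <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.hemilat_comparison <- function(x, ...) {
  tibble(
    n_outcomes = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    covariates = paste(attr(x, "covariates"), collapse = ", ")
  )
}

#' Correlate asymmetry scores with age at MRI
#'
#' Per-metric Pearson correlation between the asymmetry score and
#' `age_at_mri`, two-sided, with BH correction across metrics. Metrics with
#' zero variance in either variable are flagged rather than tested.
#'
#' @inheritParams compare_lateralization
#' @return A tibble: `metric`, `n`, `r`, `p_raw`, `p_fdr`, `degenerate`.
#' @export
correlate_with_age <- function(asymmetry, cohort) {
  asym <- asymmetry[asymmetry$defined, ]
  metrics <- unique(asym$metric)
  rows <- lapply(metrics, function(m) {
    d <- dplyr::left_join(asym[asym$metric == m, c("subject_id", "as")],
                          cohort[, c("subject_id", "age_at_mri")],
                          by = "subject_id")
    d <- d[complete.cases(d), ]
    if (nrow(d) < 3 || sd(d$as) == 0 || sd(d$age_at_mri) == 0) {
      return(tibble(metric = m, n = nrow(d), r = NA_real_,
                    p_raw = NA_real_, degenerate = TRUE))
    }
    ct <- cor.test(d$as, d$age_at_mri, method = "pearson")
    tibble(metric = m, n = nrow(d), r = unname(ct$estimate),
           p_raw = ct$p.value, degenerate = FALSE)
  })
  out <- bind_rows(rows)
  out$p_fdr <- NA_real_
  ok <- !out$degenerate
  # p.adjust directly: an exact linear fit yields p = 0, which the strict
  # (0, 1] contract of fdr_bh() would reject
  out$p_fdr[ok] <- p.adjust(out$p_raw[ok], method = "BH")
  out[, c("metric", "n", "r", "p_raw", "p_fdr", "degenerate")]
}

#' Subgroup comparison by Bayley social-emotional delay
#'
#' Among assessed preterm subjects, compares asymmetry scores between the
#' abnormal (`bayley_se < 85`, more than 1 SD below the normative mean) and
#' normal subgroups, adjusting for gestational age and age at MRI, with BH
#' correction across all tested metrics (one family, mirroring how a single
#' subgroup figure reports them).
#'
#' @inheritParams compare_lateralization
#' @param covariates Default `c("gestational_age", "age_at_mri")`.
#' @return A `hemilat_comparison` tibble (group levels abnormal vs normal).
#' @export
subgroup_compare <- function(asymmetry, cohort,
                             covariates = c("gestational_age", "age_at_mri"),
                             alpha = 0.05) {
  sub <- cohort[cohort$group == "preterm" & cohort$assessed, ]
  if (length(unique(sub$se_subgroup)) < 2 || any(table(sub$se_subgroup) < 2)) {
    abort("Subgroup comparison needs >= 2 assessed preterm subjects per Bayley-SE subgroup.",
          class = "hemilat_input_error")
  }
  asym <- asymmetry[asymmetry$subject_id %in% sub$subject_id, ]
  out <- compare_lateralization(asym, sub, group_var = "se_subgroup",
                                covariates = covariates, alpha = alpha)
  # a single FDR family across all subgroup outcomes
  out$p_fdr <- fdr_bh(out$p_raw)
  out$significant <- out$p_fdr < alpha
  out$family <- "subgroup"
  out
}

#' Sample size for comparing two proportions
#'
#' Pooled normal-approximation formula for a two-sided two-proportion z-test:
#' `n = (z_{1-alpha/2} sqrt(2 p q) + z_{power} sqrt(p1 q1 + p2 q2))^2 /
#' (p1 - p2)^2` per group, with `p` the pooled proportion, rounded up, and
#' inflated by `1 / (1 - dropout)` for attrition.
#'
#' @param p1,p2 Expected proportions (distinct, strictly inside (0, 1)).
#' @param alpha Two-sided type-I error level.
#' @param power Target power.
#' @param dropout Expected dropout fraction in `[0, 1)`.
#' @return A tibble: `n_per_group`, `n_total`, `n_per_group_dropout`,
#'   `n_total_dropout`.
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.8,
                                        dropout = 0.1) {
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    abort("Proportions must lie strictly inside (0, 1).",
          class = "hemilat_input_error")
  }
  if (p1 == p2) {
    abort("Proportions must differ.", class = "hemilat_input_error")
  }
  if (dropout < 0 || dropout >= 1) {
    abort("`dropout` must lie in [0, 1).", class = "hemilat_input_error")
  }
  pbar <- (p1 + p2) / 2
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  n_per <- ceiling(n)
  n_per_drop <- ceiling(n_per / (1 - dropout))
  tibble(
    n_per_group = n_per,
    n_total = 2L * n_per,
    n_per_group_dropout = n_per_drop,
    n_total_dropout = 2L * n_per_drop
  )
}

#' Cohort attrition arithmetic
#'
#' Tracks how an analytic sample is reached from a recruited sample through
#' named removal stages.
#'
#' @param recruited Number recruited.
#' @param removals Named integer vector of subjects removed at each stage.
#' @return A tibble with one row per stage (`stage`, `removed`, `remaining`);
#'   the last `remaining` value is the analytic n.
#' @examples
#' cohort_attrition(83, c(exclusion_criteria = 8, image_quality = 11))
#' @export
cohort_attrition <- function(recruited, removals) {
  if (is.null(names(removals)) || any(names(removals) == "")) {
    abort("`removals` must be a named vector.", class = "hemilat_input_error")
  }
  remaining <- recruited - cumsum(removals)
  if (any(remaining < 0)) {
    abort("Removals exceed the recruited sample.", class = "hemilat_input_error")
  }
  tibble(
    stage = c("recruited", names(removals)),
    removed = c(0L, as.integer(removals)),
    remaining = as.integer(c(recruited, remaining))
  )
}

#' Percentage from a count
#'
#' @param x Count of events.
#' @param n Denominator.
#' @param digits Decimal places (default 1, the usual table precision).
#' @return `round(100 * x / n, digits)`.
#' @examples
#' proportion_pct(13, 57)
#' @export
proportion_pct <- function(x, n, digits = 1) {
  if (n <= 0) abort("Denominator must be positive.", class = "hemilat_input_error")
  round(100 * x / n, digits)
}
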