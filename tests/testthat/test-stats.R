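# Statistical stage: exact tests against enumeration oracles, GLM behaviour,
# FDR arithmetic, subgroup machinery, sample-size formula.

test_that("Fisher's exact test matches hypergeometric enumeration on small tables", {
  # the Bayley-SE delay table (13/57 vs 0/21): exact p = 0.0155, frozen from
  # the enumeration oracle
  expect_equal(fisher_exact_2x2(13, 44, 0, 21),
               oracle_fisher(13, 44, 0, 21), tolerance = 1e-9)
  expect_equal(round(fisher_exact_2x2(13, 44, 0, 21), 3), 0.016)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  set.seed(3)
  for (i in 1:40) {
    cells <- rpois(4, 4)
    m <- matrix(cells, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(cells[1], cells[3], cells[2], cells[4]),
                 oracle_fisher(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(0, 0, 3, 4), class = "hemilat_input_error")
  expect_error(fisher_exact_2x2(1, -2, 3, 4), class = "hemilat_input_error")
})

test_that("chi-square matches the hand formula and Yates shrinks the statistic", {
  # N(ad-bc)^2 / (r1 r2 c1 c2) on the Bayley-SE table
  hand <- 78 * (13 * 21 - 44 * 0)^2 / (57 * 21 * 13 * 65)
  res <- chi_square_2x2(13, 44, 0, 21, yates = FALSE)
  expect_equal(res$statistic, hand, tolerance = 1e-9)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  set.seed(9)
  for (i in 1:20) {
    cells <- rpois(4, 6) + 1
    plain <- chi_square_2x2(cells[1], cells[2], cells[3], cells[4])$statistic
    yates <- chi_square_2x2(cells[1], cells[2], cells[3], cells[4],
                            yates = TRUE)$statistic
    expect_lte(yates, plain + 1e-12)
  }
})

test_that("group tests give p = 1 on identical groups and match the pooled-t closed form", {
  vals <- c(1, 2, 3, 1, 2, 3)
  grp <- rep(c("a", "b"), each = 3)
  expect_equal(group_test(vals, grp, "student_t"), 1)
  expect_equal(group_test(vals, grp, "mann_whitney"), 1)
  # pooled t on (1,2,3) vs (4,5,6): t = -3/sqrt(2/3), df = 4
  t_stat <- -3 / sqrt(1 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(t_stat, df = 4)
  expect_equal(group_test(c(1, 2, 3, 4, 5, 6), grp, "student_t"), p_hand)
  # power: a 2-SD shift at n = 50/50 is essentially always detected
  set.seed(17)
  hits <- sum(vapply(1:60, function(i) {
    x <- rnorm(50)
    y <- rnorm(50, 2)
    group_test(c(x, y), rep(c("a", "b"), each = 50), "student_t") < 0.001
  }, logical(1)))
  expect_gte(hits, 59)
  expect_error(group_test(1:3, c("a", "a", "b")), class = "hemilat_input_error")
})

test_that("BH adjustment reproduces the step-up hand computation and its properties", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  p <- runif(25)
  q <- fdr_bh(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(fdr_bh(c(0.5, 0)), class = "hemilat_input_error")
})

test_that("the adjusted comparison reduces to the pooled t-test without covariates", {
  set.seed(4)
  d <- tibble::tibble(
    y = rnorm(40),
    group = rep(c("preterm", "term"), each = 20)
  )
  res <- glm_adjusted_compare(d, "y", covariates = character())
  p_t <- t.test(y ~ group, data = d, var.equal = TRUE)$p.value
  expect_equal(res$p_raw, p_t, tolerance = 1e-9)
  # orthogonal covariates barely move the group p-value
  d$z <- rnorm(40)
  res_z <- glm_adjusted_compare(d, "y", covariates = "z")
  expect_lt(abs(res_z$p_raw - p_t), 0.05)
  # collinear covariates named
  d$z2 <- d$z * 2
  expect_error(glm_adjusted_compare(d, "y", covariates = c("z", "z2")),
               regexp = "z2", class = "hemilat_input_error")
})

test_that("adjustment recovers a confounded group effect and is calibrated under the null", {
  set.seed(8)
  delta <- 2
  recovered <- replicate(100, {
    n <- 60
    group <- rep(c(0, 1), each = n / 2)
    confounder <- rnorm(n) + 1.5 * group
    y <- delta * group + 2 * confounder + rnorm(n)
    d <- tibble::tibble(y = y, group = ifelse(group == 1, "preterm", "term"),
                        x = confounder)
    adj <- glm_adjusted_compare(d, "y", covariates = "x")$effect
    unadj <- glm_adjusted_compare(d, "y", covariates = character())$effect
    abs(abs(adj) - delta) < abs(abs(unadj) - delta)
  })
  expect_gte(mean(recovered), 0.9)

  # null calibration: group CI covers 0 at ~95%; 2-SE binomial band
  set.seed(9)
  covered <- replicate(100, {
    n <- 50
    d <- tibble::tibble(
      y = 2 * rnorm(n) + rnorm(n),
      group = sample(rep(c("preterm", "term"), n / 2)),
      x = rnorm(n)
    )
    r <- glm_adjusted_compare(d, "y", covariates = "x")
    abs(r$effect) < qt(0.975, n - 3) * r$se
  })
  expect_gte(mean(covered), 0.95 - 2 * sqrt(0.95 * 0.05 / 100))
})

test_that("compare_lateralization applies per-family FDR and carries group sizes", {
  set.seed(12)
  metrics <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", 1:30),
    hemisphere = c("left", "right"),
    metric = hemilat:::metric_keys()
  )
  metrics$value <- runif(nrow(metrics), 0.5, 1.5)
  asym <- lateralize_cohort(metrics)
  cohort <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:30),
    group = rep(c("preterm", "term"), c(18, 12)),
    sex = sample(c("male", "female"), 30, TRUE),
    age_at_mri = rnorm(30, 38),
    bpd = sample(c("yes", "no"), 30, TRUE)
  )
  comp <- compare_lateralization(asym, cohort)
  expect_s3_class(comp, "hemilat_comparison")
  expect_equal(nrow(comp), 9)
  expect_setequal(unique(comp$family), c("global", "roi_betweenness"))
  expect_true(all(comp$p_fdr >= comp$p_raw - 1e-12))
  expect_true(all(comp$n1 == 18 & comp$n2 == 12))
  # FDR applied within family: adjusting global p-values alone reproduces them
  glob <- comp[comp$family == "global", ]
  expect_equal(glob$p_fdr, fdr_bh(glob$p_raw))
  expect_equal(glance(comp)$n_outcomes, 9)
})

test_that("age correlation flags degenerate metrics and finds a perfect linear trend", {
  cohort <- tibble::tibble(subject_id = sprintf("S%02d", 1:20),
                           age_at_mri = seq(36, 41, length.out = 20))
  asym <- tibble::tibble(
    subject_id = rep(cohort$subject_id, 2),
    metric = rep(c("sigma", "lp"), each = 20),
    x_left = 1, x_right = 1,
    as = c(2 * cohort$age_at_mri - 70, rep(5, 20)),
    defined = TRUE
  )
  res <- correlate_with_age(asym, cohort)
  expect_equal(res$r[res$metric == "sigma"], 1, tolerance = 1e-9)
  expect_true(res$degenerate[res$metric == "lp"])
  expect_true(is.na(res$r[res$metric == "lp"]))

  # null calibration: mean r over independent replicates is ~0
  set.seed(31)
  rs <- replicate(100, {
    a <- asym[asym$metric == "sigma", ]
    a$as <- rnorm(20)
    correlate_with_age(a, cohort)$r
  })
  expect_lt(abs(mean(rs)), 2 / sqrt(20))
})

# build an assessed-preterm cohort + asymmetry records for subgroup tests
make_subgroup_fixture <- function(seed, mfog_shift = 0) {
  set.seed(seed)
  n_ab <- 13; n_no <- 44
  cohort <- tibble::tibble(
    subject_id = sprintf("P%02d", 1:(n_ab + n_no)),
    group = "preterm",
    assessed = TRUE,
    se_subgroup = rep(c("abnormal", "normal"), c(n_ab, n_no)),
    gestational_age = rnorm(n_ab + n_no, 30, 3),
    age_at_mri = rnorm(n_ab + n_no, 37.3, 1.3)
  )
  asym <- tidyr::expand_grid(subject_id = cohort$subject_id,
                             metric = hemilat:::metric_keys())
  asym$x_left <- 1; asym$x_right <- 1
  asym$as <- rnorm(nrow(asym))
  shift_rows <- asym$metric == "bc_mfog" &
    asym$subject_id %in% cohort$subject_id[cohort$se_subgroup == "abnormal"]
  asym$as[shift_rows] <- asym$as[shift_rows] + mfog_shift
  asym$defined <- TRUE
  list(cohort = cohort, asym = asym)
}

test_that("subgroup comparison reports 13/44 sizes, controls the null, and detects a planted shift", {
  fx <- make_subgroup_fixture(1)
  res <- subgroup_compare(fx$asym, fx$cohort)
  expect_equal(unique(res$n1), 13)  # abnormal
  expect_equal(unique(res$n2), 44)
  expect_equal(nrow(res), 9)

  # null: family false-positive rate within 0.05 + 2*MC-SE over 100 replicates
  any_sig <- vapply(1:100, function(s) {
    fx <- make_subgroup_fixture(100 + s)
    any(subgroup_compare(fx$asym, fx$cohort)$significant)
  }, logical(1))
  expect_lte(mean(any_sig), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))

  # power: a 1.5-SD mFOG shift is detected in >= 80/100 replicates
  hit <- vapply(1:100, function(s) {
    fx <- make_subgroup_fixture(300 + s, mfog_shift = 1.5)
    r <- subgroup_compare(fx$asym, fx$cohort)
    r$significant[r$metric == "bc_mfog"]
  }, logical(1))
  expect_gte(sum(hit), 80)

  # degenerate subgroup split is an input error
  bad <- fx$cohort
  bad$se_subgroup <- "normal"
  expect_error(subgroup_compare(fx$asym, bad), class = "hemilat_input_error")
})

test_that("two-proportion sample size follows the pooled formula and simulation-backed power", {
  res <- sample_size_two_proportions(0.15, 0.40, 0.05, 0.8, 0.10)
  # hand computation of the pooled normal-approximation formula
  pbar <- 0.275
  n_hand <- ceiling((qnorm(0.975) * sqrt(2 * pbar * 0.725) +
                       qnorm(0.8) * sqrt(0.15 * 0.85 + 0.40 * 0.60))^2 / 0.25^2)
  expect_equal(res$n_per_group, n_hand)
  expect_equal(res$n_total, 2 * n_hand)
  expect_equal(res$n_per_group_dropout, ceiling(n_hand / 0.9))

  # monotonicity in power
  n_seq <- vapply(c(0.7, 0.8, 0.9, 0.95), function(pw)
    sample_size_two_proportions(0.15, 0.40, power = pw)$n_per_group, numeric(1))
  expect_true(all(diff(n_seq) > 0))

  # simulation oracle: empirical power of the two-proportion z-test at the
  # returned n reaches the target within 0.03 (2000 trials)
  set.seed(19)
  n <- res$n_per_group
  hits <- replicate(2000, {
    x1 <- rbinom(1, n, 0.15)
    x2 <- rbinom(1, n, 0.40)
    p1 <- x1 / n; p2 <- x2 / n; pp <- (x1 + x2) / (2 * n)
    z <- (p2 - p1) / sqrt(2 * pp * (1 - pp) / n)
    abs(z) > qnorm(0.975)
  })
  expect_gte(mean(hits), 0.8 - 0.03)

  expect_error(sample_size_two_proportions(0.2, 0.2),
               class = "hemilat_input_error")
  expect_error(sample_size_two_proportions(0, 0.4),
               class = "hemilat_input_error")
})

test_that("cohort attrition and percentage helpers do the printed arithmetic", {
  flow <- cohort_attrition(83, c(exclusion_criteria = 8, image_quality = 11))
  expect_equal(flow$remaining, c(83, 75, 64))
  expect_equal(proportion_pct(13, 57), 22.8)
  expect_equal(proportion_pct(24, 57), 42.1)
  expect_error(cohort_attrition(10, c(a = 20)), class = "hemilat_input_error")
})
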