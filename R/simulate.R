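# Synthetic-cohort generator. Defaults emulate the study conditions this
# package targets: 64 preterm + 33 term subjects, 32 regions per hemisphere,
# binary intra-hemispheric networks from the small-world (rewired ring
# lattice) family, covariates drawn from the cohort-table summary statistics,
# and an asymmetry plant that acts on topology (hemisphere-specific rewiring
# and ROI edge attachment), never on the computed metrics directly.

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator with defaults matching a neonatal
#' preterm-vs-term DTI connectome study: group sizes 64/33, 32 nodes per
#' hemisphere, a rewired ring-lattice substrate whose density and rewiring
#' probability put the global metrics in the range typical of neonatal
#' hemispheric networks, and covariate distributions (gestational age, age at
#' MRI, sex, bronchopulmonary dysplasia, Bayley-III composites) with
#' group-specific means and spreads.
#'
#' Asymmetry is planted mechanistically, only in the preterm group:
#' * `sigma_shift_rewire` (probability units) is subtracted from the left
#'   hemisphere's rewiring probability and added to the right's, in equal
#'   halves; a positive value yields leftward small-worldness asymmetry.
#' * `density_shift` (density units, left minus right) offsets the two
#'   hemispheres' edge densities.
#' * `roi_extra_edges` attaches that many extra edges to the named ROI node
#'   in the left hemisphere (balanced by removing the same number of edges
#'   elsewhere), raising its betweenness.
#'
#' @param n_preterm,n_term Group sizes (>= 1).
#' @param nodes_per_hemisphere Regions per hemisphere (default 32).
#' @param intra_edge_density Target edge density of each hemisphere in (0, 1].
#' @param rewire_prob_left,rewire_prob_right Baseline Watts-Strogatz rewiring
#'   probabilities (applied to all subjects).
#' @param sigma_shift_rewire,density_shift,roi_extra_edges Preterm-only
#'   asymmetry plant, see Details.
#' @param interhemispheric_density Probability of each left-right edge.
#' @param fa_mean,fa_sd Truncated-normal FA distribution on existing edges.
#' @param fibers_per_edge_mean Poisson rate for per-edge streamline counts
#'   (zero-truncated so every edge has at least one fiber).
#' @param covariates Named list of covariate distribution parameters; see the
#'   default for the expected structure (`c(mean, sd)` pairs or proportions
#'   per group).
#' @param max_attempts Connectivity retries per hemisphere graph.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_preterm = 64L,
                       n_term = 33L,
                       nodes_per_hemisphere = 32L,
                       intra_edge_density = 0.32,
                       rewire_prob_left = 0.15,
                       rewire_prob_right = 0.15,
                       sigma_shift_rewire = 0,
                       density_shift = 0,
                       roi_extra_edges = c(mfog = 0L, stg = 0L,
                                           amygdala = 0L, hippocampus = 0L),
                       interhemispheric_density = 0.05,
                       fa_mean = 0.25,
                       fa_sd = 0.05,
                       fibers_per_edge_mean = 5,
                       covariates = default_covariate_distributions(),
                       max_attempts = 100L) {
  cfg <- list(
    n_preterm = as.integer(n_preterm),
    n_term = as.integer(n_term),
    nodes_per_hemisphere = as.integer(nodes_per_hemisphere),
    intra_edge_density = intra_edge_density,
    rewire_prob_left = rewire_prob_left,
    rewire_prob_right = rewire_prob_right,
    sigma_shift_rewire = sigma_shift_rewire,
    density_shift = density_shift,
    roi_extra_edges = roi_extra_edges,
    interhemispheric_density = interhemispheric_density,
    fa_mean = fa_mean,
    fa_sd = fa_sd,
    fibers_per_edge_mean = fibers_per_edge_mean,
    covariates = covariates,
    max_attempts = as.integer(max_attempts)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default covariate distribution parameters
#'
#' Group-specific means and SDs for gestational age and age at MRI (weeks),
#' male-sex and bronchopulmonary-dysplasia proportions, Bayley-III composite
#' scores (cognitive, language, motor, social-emotional; norm mean 100,
#' SD 15), and the fraction of each group with a completed assessment.
#'
#' @return A named list consumed by [sim_config()].
#' @export
default_covariate_distributions <- function() {
  list(
    ga = list(preterm = c(mean = 30.08, sd = 3.94, lo = 23, hi = 36.9),
              term    = c(mean = 38.39, sd = 1.22, lo = 37, hi = 42)),
    age_at_mri = list(preterm = c(mean = 37.30, sd = 1.33, lo = 36, hi = 41),
                      term    = c(mean = 38.61, sd = 0.86, lo = 36, hi = 41)),
    male_prop = c(preterm = 0.394, term = 0.348),
    bpd_prev = c(preterm = 0.453, term = 0),
    assessed_prop = c(preterm = 57 / 64, term = 21 / 33),
    bayley = list(
      cognitive = list(preterm = c(mean = 95.47, sd = 14.47),
                       term    = c(mean = 102.38, sd = 8.74)),
      language  = list(preterm = c(mean = 89.21, sd = 15.42),
                       term    = c(mean = 93.95, sd = 6.68)),
      motor     = list(preterm = c(mean = 95.38, sd = 16.41),
                       term    = c(mean = 105.04, sd = 11.03)),
      se        = list(preterm = c(mean = 97.28, sd = 17.39),
                       term    = c(mean = 108.57, sd = 11.95))
    )
  )
}

validate_sim_config <- function(cfg) {
  if (cfg$n_preterm < 1 || cfg$n_term < 1) {
    abort("Group sizes must be >= 1.", class = "hemilat_config_error")
  }
  if (cfg$nodes_per_hemisphere < 4) {
    abort("`nodes_per_hemisphere` must be >= 4.", class = "hemilat_config_error")
  }
  probs <- c(cfg$rewire_prob_left, cfg$rewire_prob_right,
             cfg$interhemispheric_density)
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must lie in [0, 1].", class = "hemilat_config_error")
  }
  if (cfg$intra_edge_density <= 0 || cfg$intra_edge_density > 1) {
    abort("`intra_edge_density` must lie in (0, 1].", class = "hemilat_config_error")
  }
  if (cfg$fa_mean <= 0 || cfg$fa_mean >= 1 ||
      cfg$fa_mean - 3 * cfg$fa_sd <= 0 || cfg$fa_mean + 3 * cfg$fa_sd >= 1) {
    abort("FA distribution must keep mean +/- 3 SD inside (0, 1).",
          class = "hemilat_config_error")
  }
  invisible(cfg)
}

# Inverse-CDF truncated normal: a fixed number of RNG draws per value, which
# keeps subject streams aligned regardless of acceptance/rejection.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Simulate a cohort covariate table
#'
#' Draws one row per subject: group, sex, gestational age (preterm strictly
#' below the term range), age at MRI, bronchopulmonary dysplasia flag, an
#' assessment-completed flag, Bayley-III composite scores (only when
#' assessed), and the social-emotional subgroup flag (`"abnormal"` when the
#' SE composite is below 85, i.e. more than 1 SD below the normative mean).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per subject.
#' @examples
#' tab <- simulate_cohort_table(sim_config(n_preterm = 8, n_term = 4), seed = 1)
#' dplyr::count(tab, group)
#' @export
simulate_cohort_table <- function(config = sim_config(), seed = 1L) {
  validate_sim_config(config)
  cv <- config$covariates
  with_seed(seed, {
    groups <- c(rep("preterm", config$n_preterm), rep("term", config$n_term))
    n <- length(groups)
    draw_by_group <- function(param) {
      vapply(seq_len(n), function(i) {
        p <- param[[groups[i]]]
        rnorm_trunc(1, p["mean"], p["sd"], p["lo"] %||% -Inf, p["hi"] %||% Inf)
      }, numeric(1))
    }
    ga <- draw_by_group(cv$ga)
    age_mri <- draw_by_group(cv$age_at_mri)
    sex <- ifelse(runif(n) < cv$male_prop[groups], "male", "female")
    bpd <- ifelse(runif(n) < cv$bpd_prev[groups], "yes", "no")
    assessed <- runif(n) < cv$assessed_prop[groups]
    draw_bayley <- function(domain) {
      raw <- vapply(seq_len(n), function(i) {
        p <- cv$bayley[[domain]][[groups[i]]]
        rnorm(1, p["mean"], p["sd"])
      }, numeric(1))
      ifelse(assessed, round(raw, 1), NA_real_)
    }
    tab <- tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = groups,
      sex = sex,
      gestational_age = round(ga, 2),
      age_at_mri = round(age_mri, 2),
      bpd = bpd,
      assessed = assessed,
      bayley_cognitive = draw_bayley("cognitive"),
      bayley_language = draw_bayley("language"),
      bayley_motor = draw_bayley("motor"),
      bayley_se = draw_bayley("se")
    )
    tab$se_subgroup <- ifelse(
      tab$assessed, ifelse(tab$bayley_se < 85, "abnormal", "normal"),
      NA_character_)
    tab
  })
}

#' Simulate one intra-hemispheric binary network
#'
#' Watts-Strogatz construction: a ring lattice at the closest achievable
#' density (each node linked to its `2 * nei` nearest neighbours) with each
#' edge rewired with probability `rewire_prob`, retried until the result is
#' connected.
#'
#' @param n_nodes Number of nodes (>= 4).
#' @param density Target edge density; the lattice uses
#'   `nei = round(density * (n_nodes - 1) / 2)` neighbours per side, which
#'   must be >= 1 and < n_nodes / 2.
#' @param rewire_prob Per-edge rewiring probability.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param max_attempts Connectivity retries before giving up.
#' @return A `hemisphere_network` (side `"unspecified"`); the number of
#'   attempts used is attached as attribute `"attempts"`.
#' @export
simulate_hemisphere_graph <- function(n_nodes, density, rewire_prob,
                                      seed = NULL, max_attempts = 100L) {
  if (n_nodes < 4) {
    abort("`n_nodes` must be >= 4.", class = "hemilat_config_error")
  }
  nei <- round(density * (n_nodes - 1) / 2)
  if (nei < 1 || nei >= n_nodes / 2) {
    abort(sprintf(
      "Density %.3f is not achievable as a ring lattice on %d nodes.",
      density, n_nodes), class = "hemilat_config_error")
  }
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      g <- igraph::sample_smallworld(1, n_nodes, nei, rewire_prob,
                                     loops = FALSE, multiple = FALSE)
      if (igraph::is_connected(g)) {
        if (attempt > 1) {
          inform(sprintf(
            "simulate_hemisphere_graph: connected after %d attempt(s).", attempt))
        }
        adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
        net <- new_hemisphere_network("unspecified", seq_len(n_nodes), adj)
        attr(net, "attempts") <- attempt
        return(net)
      }
    }
    abort(sprintf("No connected graph in %d attempts (n=%d, density=%.3f, p=%.2f).",
                  max_attempts, n_nodes, density, rewire_prob),
          class = "hemilat_generation_error")
  })
}

# Add `extra` edges incident to node `roi`, removing the same number of
# non-incident edges whose removal keeps the graph connected.
boost_roi_node <- function(adj, roi, extra) {
  if (extra <= 0) return(adj)
  n <- nrow(adj)
  non_nb <- setdiff(which(adj[roi, ] == 0), roi)
  add <- sample(non_nb, min(extra, length(non_nb)))
  adj[roi, add] <- adj[add, roi] <- 1L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  edges <- igraph::as_edgelist(g)
  cand <- which(edges[, 1] != roi & edges[, 2] != roi)
  removed <- 0L
  for (e in sample(cand)) {
    if (removed >= length(add)) break
    i <- edges[e, 1]; j <- edges[e, 2]
    adj[i, j] <- adj[j, i] <- 0L
    gi <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::is_connected(gi)) {
      removed <- removed + 1L
    } else {
      adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

group_hemisphere_params <- function(config, group) {
  d <- config$intra_edge_density
  pl <- config$rewire_prob_left
  pr <- config$rewire_prob_right
  dl <- dr <- d
  if (group == "preterm") {
    pl <- min(max(pl - config$sigma_shift_rewire / 2, 0), 1)
    pr <- min(max(pr + config$sigma_shift_rewire / 2, 0), 1)
    dl <- d + config$density_shift / 2
    dr <- d - config$density_shift / 2
  }
  list(density_left = dl, density_right = dr,
       rewire_left = pl, rewire_right = pr)
}

#' Simulate one subject's connectome
#'
#' Generates left and right intra-hemispheric Watts-Strogatz networks (with
#' the preterm-only asymmetry plant of [sim_config()] applied when the
#' subject's group is `"preterm"`), sprinkles sparse interhemispheric edges,
#' and dresses existing edges with truncated-normal FA weights and
#' zero-truncated Poisson fiber counts.
#'
#' @param config A [sim_config()].
#' @param subject_row One row of a [simulate_cohort_table()] tibble.
#' @param seed Integer seed for this subject.
#' @return A `connectome`; the generative parameters and the exact left/right
#'   block adjacencies are attached as attribute `"truth"`.
#' @export
simulate_connectome <- function(config, subject_row, seed = NULL) {
  validate_sim_config(config)
  nh <- config$nodes_per_hemisphere
  atlas <- neonatal_atlas(nh)
  par <- group_hemisphere_params(config, subject_row$group)
  with_seed(seed, {
    left <- simulate_hemisphere_graph(nh, par$density_left, par$rewire_left,
                                      max_attempts = config$max_attempts)
    right <- simulate_hemisphere_graph(nh, par$density_right, par$rewire_right,
                                       max_attempts = config$max_attempts)
    ladj <- left$adjacency
    if (subject_row$group == "preterm") {
      rois <- c("mfog", "stg", "amygdala", "hippocampus")
      for (r in rois) {
        extra <- config$roi_extra_edges[[r]] %||% 0L
        if (extra > 0) {
          node <- which(atlas$roi_flag == r & atlas$hemisphere == "left")
          ladj <- boost_roi_node(ladj, node, extra)
        }
      }
    }
    radj <- right$adjacency
    n <- 2L * nh
    binary <- matrix(0L, n, n)
    binary[seq_len(nh), seq_len(nh)] <- ladj
    binary[nh + seq_len(nh), nh + seq_len(nh)] <- radj
    cross <- matrix(runif(nh * nh) < config$interhemispheric_density, nh, nh)
    binary[seq_len(nh), nh + seq_len(nh)] <- cross * 1L
    binary[nh + seq_len(nh), seq_len(nh)] <- t(cross) * 1L
    diag(binary) <- 0L

    counts <- matrix(0L, n, n)
    fa <- matrix(0, n, n)
    up <- which(upper.tri(binary) & binary == 1L)
    k <- length(up)
    # zero-truncated Poisson via inverse CDF conditioned away from 0
    lam <- config$fibers_per_edge_mean
    u <- runif(k, exp(-lam), 1)
    counts[up] <- stats::qpois(u, lam)
    fa[up] <- rnorm_trunc(k, config$fa_mean, config$fa_sd, 0, 1)
    counts <- counts + t(counts)
    storage.mode(counts) <- "integer"
    fa <- fa + t(fa)
    dimnames(counts) <- dimnames(fa) <- list(atlas$label_id, atlas$label_id)

    conn <- new_connectome(subject_row$subject_id, atlas$label_id, fa, counts)
    attr(conn, "truth") <- list(
      group = subject_row$group, params = par,
      left_adjacency = ladj, right_adjacency = radj,
      attempts = c(left = attr(left, "attempts"),
                   right = attr(right, "attempts")))
    conn
  })
}

#' Simulate a streamline set from a connectome
#'
#' For every existing edge, generates its recorded number of fibers, each with
#' 5-50 voxel FA samples, constructed so that the mean of the fiber means
#' equals the edge's FA weight (well within a 0.02 tolerance).
#'
#' @param connectome A `connectome` with positive fiber counts.
#' @param config A [sim_config()] (supplies nothing beyond validation here).
#' @param seed Integer seed.
#' @return A streamline tibble (`subject_id`, `label_a`, `label_b`,
#'   `voxel_fa` list-column) suitable for [build_matrix()].
#' @export
simulate_tractogram <- function(connectome, config = sim_config(), seed = NULL) {
  up <- which(upper.tri(connectome$binary) & connectome$binary == 1L,
              arr.ind = TRUE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(up)), function(e) {
      i <- up[e, 1]; j <- up[e, 2]
      n_fib <- connectome$fiber_count[i, j]
      edge_fa <- connectome$fa_weight[i, j]
      spread <- rnorm(n_fib, 0, 0.01)
      fiber_means <- edge_fa + spread - mean(spread)
      voxel_fa <- lapply(fiber_means, function(m) {
        len <- sample(5:50, 1)
        noise <- rnorm(len, 0, 0.02)
        pmin(pmax(m + noise - mean(noise), 0), 1)
      })
      tibble(
        subject_id = connectome$subject_id,
        label_a = connectome$labels[i],
        label_b = connectome$labels[j],
        fiber = seq_len(n_fib),
        voxel_fa = voxel_fa
      )
    })
    bind_rows(rows)
  })
}

# Per-subject seeds derived from the master seed by a fixed affine counter
# scheme, kept below 2^31 - 1.
subject_seed <- function(master_seed, i) {
  (as.numeric(master_seed) + 1000003 * i) %% 2147483647
}

#' Simulate a full synthetic cohort
#'
#' Covariate table plus one connectome per subject. Each subject's draws come
#' from an independent RNG stream seeded by an affine counter on the master
#' seed, so cohorts are reproducible and subjects can be regenerated in
#' isolation.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @return A `synthetic_cohort` list: `cohort_table`, `connectomes` (named by
#'   subject), `atlas`, `config`, `seed`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_preterm = 3, n_term = 2), seed = 7)
#' names(cohort$connectomes)
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  tab <- simulate_cohort_table(config, seed = seed)
  connectomes <- lapply(seq_len(nrow(tab)), function(i) {
    simulate_connectome(config, tab[i, ], seed = subject_seed(seed, i))
  })
  names(connectomes) <- tab$subject_id
  structure(
    list(cohort_table = tab, connectomes = connectomes,
         atlas = neonatal_atlas(config$nodes_per_hemisphere),
         config = config, seed = seed),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d preterm + %d term subjects, %d nodes\n",
              sum(x$cohort_table$group == "preterm"),
              sum(x$cohort_table$group == "term"),
              2L * x$config$nodes_per_hemisphere))
  invisible(x)
}
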