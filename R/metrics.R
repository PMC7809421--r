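# All measures are defined on simple, undirected, binary graphs.
# Conventions (documented in the methods vignette):
#  * Lp averages hop distances over ordered reachable pairs of the largest
#    connected component; Eglob uses 1/Inf = 0 over all ordered pairs.
#  * Nodes of degree < 2 contribute 0 to Cp and Elocal but stay in the 1/N
#    average.
#  * Betweenness is normalized by (N-1)(N-2)/2 so values live in [0, 1].

as_hemi <- function(network) {
  if (inherits(network, "hemisphere_network")) return(network)
  if (is.matrix(network)) {
    if (nrow(network) != ncol(network) || !isTRUE(all.equal(network, t(network)))) {
      abort("Adjacency matrix must be square and symmetric.",
            class = "hemilat_input_error")
    }
    labs <- if (!is.null(rownames(network))) as.integer(rownames(network)) else seq_len(nrow(network))
    return(new_hemisphere_network("unspecified", labs, (network != 0) * 1L))
  }
  abort("`network` must be a hemisphere_network or an adjacency matrix.",
        class = "hemilat_input_error")
}

# All-pairs BFS hop distances by frontier expansion with boolean matrix
# products; O(diameter * n^3) but with tiny constants at the n ~ 32 scale
# this package works at.
adj_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  visited <- diag(n) > 0
  frontier <- (A > 0) & !visited
  k <- 1
  while (any(frontier)) {
    D[frontier] <- k
    visited <- visited | frontier
    frontier <- ((frontier %*% A) > 0) & !visited
    k <- k + 1
  }
  D
}

# Per-node clustering 2 E_i / (k_i (k_i - 1)); degree < 2 contributes 0.
adj_clustering <- function(A) {
  deg <- rowSums(A)
  tri2 <- rowSums((A %*% A) * A)  # 2 * E_i
  cc <- ifelse(deg >= 2, tri2 / (deg * (deg - 1)), 0)
  as.numeric(cc)
}

adj_local_eff <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    eglob_from_dist(adj_dist(A[nb, nb, drop = FALSE]))
  }, numeric(1))
}

#' Hop-count shortest-path matrix
#'
#' Breadth-first-search distances between all node pairs of a binary network;
#' unreachable pairs are `Inf`.
#'
#' @param network A `hemisphere_network` or a symmetric binary adjacency
#'   matrix.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
shortest_path_matrix <- function(network) {
  network <- as_hemi(network)
  d <- adj_dist(network$adjacency)
  dimnames(d) <- list(network$labels, network$labels)
  d
}

lcc_nodes_adj <- function(A) {
  reach <- is.finite(adj_dist(A))
  comp_id <- integer(nrow(A))
  cur <- 0L
  for (i in seq_len(nrow(A))) {
    if (comp_id[i] == 0L) {
      cur <- cur + 1L
      comp_id[reach[i, ]] <- cur
    }
  }
  which(comp_id == which.max(tabulate(comp_id)))
}

# Workhorses on a precomputed distance matrix -------------------------------

lp_from_dist <- function(d) {
  finite <- is.finite(d) & row(d) != col(d)
  if (!any(finite)) return(NA_real_)
  # restrict to the largest component: keep rows/cols with the most finite
  # entries is wrong in general; recompute membership from reachability
  reach <- is.finite(d)
  comp_id <- integer(nrow(d))
  cur <- 0L
  for (i in seq_len(nrow(d))) {
    if (comp_id[i] == 0L) {
      cur <- cur + 1L
      comp_id[reach[i, ]] <- cur
    }
  }
  sizes <- tabulate(comp_id)
  keep <- comp_id == which.max(sizes)
  if (sum(keep) < 2) return(NA_real_)
  dk <- d[keep, keep, drop = FALSE]
  mean(dk[row(dk) != col(dk)])
}

eglob_from_dist <- function(d) {
  if (nrow(d) < 2) return(0)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (nrow(d) * (nrow(d) - 1))
}

#' Characteristic path length
#'
#' Mean shortest-path hop count over ordered node pairs. On disconnected
#' graphs the average is taken within the largest connected component (the
#' convention recorded in the result of [compute_metrics()]); a graph whose
#' largest component has fewer than two nodes has no defined path length and
#' yields `NA` with a warning.
#'
#' @inheritParams shortest_path_matrix
#' @return A single number (hops), or `NA_real_` when undefined.
#' @export
char_path_length <- function(network) {
  lp <- lp_from_dist(shortest_path_matrix(network))
  if (is.na(lp)) {
    warn("Characteristic path length undefined: no connected pair of nodes.",
         class = "hemilat_undefined_metric")
  }
  lp
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs, with the inverse
#' distance of unreachable pairs taken as 0. Defined on any graph, including
#' disconnected ones.
#'
#' @inheritParams shortest_path_matrix
#' @return A number in `[0, 1]`.
#' @export
global_efficiency <- function(network) {
  eglob_from_dist(shortest_path_matrix(network))
}

#' Clustering coefficient
#'
#' Network-level clustering: the mean over nodes of `2 * E_i / (k_i (k_i - 1))`
#' where `k_i` is the degree of node `i` and `E_i` the number of edges among
#' its neighbours. Nodes with fewer than two neighbours contribute 0 but are
#' kept in the average.
#'
#' @inheritParams shortest_path_matrix
#' @return A number in `[0, 1]`.
#' @export
clustering_coefficient <- function(network) {
  mean(adj_clustering(as_hemi(network)$adjacency))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighbourhood
#' subgraph (the induced subgraph on its neighbours, the node itself
#' excluded). Nodes with fewer than two neighbours contribute 0.
#'
#' @inheritParams shortest_path_matrix
#' @return A number in `[0, 1]`.
#' @export
local_efficiency <- function(network) {
  mean(adj_local_eff(as_hemi(network)$adjacency))
}

#' Normalized betweenness centrality
#'
#' For each node, the fraction of shortest paths between the other node pairs
#' that pass through it, normalized by the number of such pairs,
#' `(N - 1)(N - 2) / 2`, so values lie in `[0, 1]`.
#'
#' @inheritParams shortest_path_matrix
#' @return A named numeric vector (one value per node, named by label).
#' @export
betweenness_centrality <- function(network) {
  network <- as_hemi(network)
  n <- length(network$labels)
  if (n < 3) {
    abort("Betweenness requires at least 3 nodes.", class = "hemilat_input_error")
  }
  b <- igraph::betweenness(as_igraph(network), directed = FALSE)
  b <- b / ((n - 1) * (n - 2) / 2)
  names(b) <- network$labels
  b
}

#' Degree-preserving random reference network
#'
#' Rewires the network by repeated double-edge swaps that preserve every
#' node's degree, rejecting swaps that would introduce self-loops or
#' multi-edges. Connectivity of the result is not enforced. Used to build the
#' null ensemble for small-worldness.
#'
#' @inheritParams shortest_path_matrix
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param swap_factor Attempted swaps per edge (default 10).
#' @return A `hemisphere_network` with the same labels and degree sequence.
#' @export
random_reference <- function(network, seed = NULL, swap_factor = 10) {
  network <- as_hemi(network)
  g <- as_igraph(network)
  if (igraph::ecount(g) < 2) {
    warn("Network has fewer than 2 edges; returned unchanged.",
         class = "hemilat_degenerate_rewire")
    return(network)
  }
  g2 <- with_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE,
                              niter = swap_factor * igraph::ecount(g))))
  adj <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  new_hemisphere_network(network$side, network$labels, adj)
}

#' Small-worldness against a degree-matched null ensemble
#'
#' Computes the clustering coefficient `Cp` and characteristic path length
#' `Lp` of the network (its largest connected component if disconnected) and
#' compares them with the means `Cran`, `Lran` over `n_random`
#' degree-preserving random references. The default orientation is
#' `sigma = (Cp / Cran) / (Lp / Lran)`, under which small-world networks score
#' above 1; `orientation = "printed"` returns the reciprocal,
#' `(Lp / Lran) / (Cp / Cran)`, for comparison with reports that quote that
#' form.
#'
#' @inheritParams random_reference
#' @param n_random Number of random references (default 100).
#' @param orientation `"standard"` (default) or `"printed"`.
#' @return A list with `sigma`, `cp`, `lp`, `cran`, `lran`, `n_random`,
#'   `orientation` and `component_note` (NULL when the graph is connected).
#' @export
small_worldness <- function(network, n_random = 100, seed = NULL,
                            swap_factor = 10,
                            orientation = c("standard", "printed")) {
  orientation <- match.arg(orientation)
  network <- as_hemi(network)
  component_note <- NULL
  keep <- lcc_nodes_adj(network$adjacency)
  if (length(keep) < nrow(network$adjacency)) {
    component_note <- sprintf(
      "sigma computed on largest component (%d of %d nodes)",
      length(keep), nrow(network$adjacency))
    network <- new_hemisphere_network(
      network$side, network$labels[keep],
      network$adjacency[keep, keep, drop = FALSE])
  }
  g <- as_igraph(network)
  cp <- mean(adj_clustering(network$adjacency))
  lp <- lp_from_dist(adj_dist(network$adjacency))
  n_edges <- sum(network$adjacency) / 2
  refs <- with_seed(seed, lapply(seq_len(n_random), function(i) {
    r <- igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = swap_factor * n_edges))
    ra <- as.matrix(igraph::as_adjacency_matrix(r, sparse = FALSE))
    c(cp = mean(adj_clustering(ra)), lp = lp_from_dist(adj_dist(ra)))
  }))
  refs <- do.call(rbind, refs)
  cran <- mean(refs[, "cp"])
  lran <- mean(refs[, "lp"])
  if (!is.finite(cran) || cran == 0 || !is.finite(cp) || cp == 0) {
    warn("Small-worldness undefined: zero clustering in network or references.",
         class = "hemilat_undefined_metric")
    sigma <- NA_real_
  } else {
    gamma_ratio <- (cp / cran) / (lp / lran)
    sigma <- if (orientation == "standard") gamma_ratio else 1 / gamma_ratio
  }
  list(sigma = sigma, cp = cp, lp = lp, cran = cran, lran = lran,
       n_random = n_random, orientation = orientation,
       component_note = component_note)
}

#' Compute the full per-hemisphere metric set
#'
#' Bundles characteristic path length, global efficiency, clustering, local
#' efficiency, small-worldness, and per-node profiles (degree, neighbour
#' edges, local efficiency, betweenness) for one hemispheric network.
#'
#' @inheritParams small_worldness
#' @return A `network_metrics` object; use [tidy()] for a long tibble of the
#'   global measures.
#' @export
compute_metrics <- function(network, n_random = 100, seed = NULL,
                            swap_factor = 10,
                            orientation = c("standard", "printed")) {
  orientation <- match.arg(orientation)
  network <- as_hemi(network)
  A <- network$adjacency
  d <- adj_dist(A)
  deg <- rowSums(A)
  cc <- adj_clustering(A)
  sw <- small_worldness(network, n_random = n_random, seed = seed,
                        swap_factor = swap_factor, orientation = orientation)
  n <- length(network$labels)
  btw <- if (n >= 3) betweenness_centrality(network) else
    setNames(rep(NA_real_, n), network$labels)
  profiles <- tibble(
    label_id = network$labels,
    degree = as.integer(deg),
    neighbor_edges = as.integer(round(cc * deg * (deg - 1) / 2)),
    local_efficiency = adj_local_eff(A),
    betweenness = unname(btw)
  )
  structure(
    list(side = network$side,
         lp = lp_from_dist(d),
         eglob = eglob_from_dist(d),
         cp = mean(cc),
         elocal = mean(profiles$local_efficiency),
         sigma = sw$sigma,
         random_summary = sw[c("cran", "lran", "n_random")],
         node_profiles = profiles,
         component_note = sw$component_note),
    class = "network_metrics"
  )
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "<network_metrics> %s: Lp=%.3f Eglob=%.3f Cp=%.3f Elocal=%.3f sigma=%.3f\n",
    x$side, x$lp, x$eglob, x$cp, x$elocal, x$sigma))
  if (!is.null(x$component_note)) cat(" note:", x$component_note, "\n")
  invisible(x)
}

#' @rdname compute_metrics
#' @param x A `network_metrics` object.
#' @param ... Unused.
#' @export
tidy.network_metrics <- function(x, ...) {
  tibble(
    hemisphere = x$side,
    metric = c("lp", "eglob", "cp", "elocal", "sigma"),
    value = c(x$lp, x$eglob, x$cp, x$elocal, x$sigma)
  )
}

#' Betweenness of the fronto-limbic regions of interest
#'
#' Looks up the normalized betweenness of the four flagged fronto-limbic
#' regions (medial fronto-orbital gyrus, superior temporal gyrus, amygdala,
#' hippocampus) in a hemisphere's node profiles.
#'
#' @param metrics A `network_metrics` object from [compute_metrics()].
#' @param atlas Atlas label table with `roi_flag` column.
#' @return A tibble with columns `roi`, `hemisphere`, `betweenness`.
#' @export
extract_roi_betweenness <- function(metrics, atlas) {
  validate_atlas(atlas)
  rois <- c("mfog", "stg", "amygdala", "hippocampus")
  side <- metrics$side
  out <- lapply(rois, function(r) {
    lab <- atlas$label_id[atlas$roi_flag == r & atlas$hemisphere == side]
    if (length(lab) != 1 || !(lab %in% metrics$node_profiles$label_id)) {
      abort(sprintf("ROI '%s' not found in the %s hemisphere's node set.", r, side),
            class = "hemilat_input_error")
    }
    tibble(roi = r, hemisphere = side,
           betweenness = metrics$node_profiles$betweenness[
             match(lab, metrics$node_profiles$label_id)])
  })
  bind_rows(out)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
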