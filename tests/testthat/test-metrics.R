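# Graph measures against closed forms and independent brute-force oracles.

test_that("shortest paths, path length and efficiency match closed forms on canonical graphs", {
  # path a-b-c
  P3 <- make_path_graph(3)
  D <- shortest_path_matrix(P3)
  expect_equal(unname(D[1, 3]), 2)
  expect_equal(char_path_length(P3), 4 / 3)
  expect_equal(global_efficiency(P3), 5 / 6)

  # complete graphs: everything is 1
  K4 <- make_complete_graph(4)
  expect_true(all(shortest_path_matrix(K4)[row(K4) != col(K4)] == 1))
  expect_equal(char_path_length(K4), 1)
  expect_equal(global_efficiency(K4), 1)
  expect_equal(clustering_coefficient(K4), 1)
  expect_equal(local_efficiency(K4), 1)

  # 5-cycle
  expect_equal(char_path_length(make_cycle_graph(5)), 1.5)

  # two disconnected dyads: cross distances infinite, Eglob counts 1/Inf = 0
  dyads <- matrix(0L, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- dyads[3, 4] <- dyads[4, 3] <- 1L
  D <- shortest_path_matrix(dyads)
  expect_true(all(is.infinite(D[1:2, 3:4])))
  # 4 ordered pairs at distance 1 among 12 ordered pairs
  expect_equal(global_efficiency(dyads), 4 / 12)
  # Lp restricted to (a) largest component of size 2
  expect_equal(char_path_length(dyads), 1)

  # edgeless graph: Eglob 0, Lp undefined
  E3 <- matrix(0L, 3, 3)
  expect_equal(global_efficiency(E3), 0)
  expect_warning(lp <- char_path_length(E3), class = "hemilat_undefined_metric")
  expect_true(is.na(lp))
})

test_that("clustering and local efficiency follow the degree<2-contributes-0 convention", {
  expect_equal(clustering_coefficient(make_star_graph(5)), 0)
  expect_equal(local_efficiency(make_star_graph(5)), 0)
  # triangle plus pendant: clustering (1+1+1+0)/4, pendant node counts in N
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- A[1, 3] <- A[3, 1] <- A[2, 3] <- A[3, 2] <- 1L
  A[3, 4] <- A[4, 3] <- 1L
  expect_equal(clustering_coefficient(A), oracle_cp(A))
  expect_equal(clustering_coefficient(A), (1 + 1 + 1 / 3 + 0) / 4)
})

test_that("betweenness matches geodesic enumeration on canonical graphs", {
  b_star <- betweenness_centrality(make_star_graph(5))
  expect_equal(unname(b_star), c(1, 0, 0, 0, 0))
  b_path <- betweenness_centrality(make_path_graph(3))
  expect_equal(unname(b_path[2]), 1)
  b_cycle <- betweenness_centrality(make_cycle_graph(5))
  expect_equal(unname(b_cycle), rep(1 / 6, 5), tolerance = 1e-12)
  expect_equal(unname(b_cycle), oracle_betweenness(make_cycle_graph(5)),
               tolerance = 1e-12)
})

test_that("all five measures and betweenness agree with brute-force oracles on every connected 4-node graph and sampled 5-node graphs", {
  graphs4 <- all_connected_graphs(4)
  expect_gt(length(graphs4), 30)
  for (A in graphs4) {
    expect_equal(char_path_length(A), oracle_lp(A))
    expect_equal(global_efficiency(A), oracle_eglob(A))
    expect_equal(clustering_coefficient(A), oracle_cp(A))
    expect_equal(local_efficiency(A), oracle_elocal(A))
    expect_equal(unname(betweenness_centrality(A)), oracle_betweenness(A),
                 tolerance = 1e-12)
  }
  # 5-node: spot-check a deterministic subsample (full sweep runs in the
  # acceptance suite)
  graphs5 <- all_connected_graphs(5)
  idx <- seq(1, length(graphs5), by = 17)
  for (A in graphs5[idx]) {
    expect_equal(char_path_length(A), oracle_lp(A))
    expect_equal(unname(betweenness_centrality(A)), oracle_betweenness(A),
                 tolerance = 1e-12)
  }
})

test_that("global measures are invariant under node permutation and Eglob is edge-monotone", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.5)
    A <- A + t(A)
    p <- sample(n)
    B <- A[p, p]
    expect_equal(global_efficiency(A), global_efficiency(B))
    expect_equal(clustering_coefficient(A), clustering_coefficient(B))
    expect_equal(local_efficiency(A), local_efficiency(B))
    # add one absent edge: Eglob never decreases
    absent <- which(A == 0 & row(A) < col(A))
    if (length(absent) > 0) {
      e <- absent[sample.int(length(absent), 1)]
      A2 <- A
      A2[e] <- 1L
      A2 <- pmax(A2, t(A2))
      expect_gte(global_efficiency(A2), global_efficiency(A))
    }
  }
})

test_that("random references preserve the degree sequence and edge count exactly", {
  set.seed(5)
  lat <- make_ring_lattice(32, 4)
  for (s in 1:10) {
    ref <- random_reference(lat, seed = s)
    expect_equal(unname(rowSums(ref$adjacency)), rowSums(lat))
    expect_equal(sum(ref$adjacency), sum(lat))
    expect_true(all(diag(ref$adjacency) == 0))
  }
  # rewiring destroys lattice clustering on average
  cls <- vapply(1:30, function(s)
    clustering_coefficient(random_reference(lat, seed = s)$adjacency),
    numeric(1))
  expect_lt(mean(cls), clustering_coefficient(lat))
})

test_that("small-worldness is ~1 on degree-matched random graphs and >1 on a ring lattice", {
  lat <- make_ring_lattice(32, 4)
  sw_lat <- small_worldness(lat, n_random = 50, seed = 101)
  expect_gt(sw_lat$sigma, 1)
  # randomized graphs measured against their own null ensemble: a single
  # sparse graph is noisy, so assert the Monte-Carlo mean over 20 graphs
  sig_rnd <- vapply(1:20, function(s) {
    rnd <- random_reference(lat, seed = 70 + s, swap_factor = 30)
    suppressWarnings(small_worldness(rnd, n_random = 20, seed = 102 + s)$sigma)
  }, numeric(1))
  expect_lt(abs(mean(sig_rnd, na.rm = TRUE) - 1), 0.12)
  # printed orientation is the exact reciprocal given shared references
  sw_std <- small_worldness(lat, n_random = 20, seed = 9, orientation = "standard")
  sw_pr <- small_worldness(lat, n_random = 20, seed = 9, orientation = "printed")
  expect_equal(sw_std$sigma * sw_pr$sigma, 1, tolerance = 1e-12)
  expect_equal(sw_std$cran, sw_pr$cran)
  # bit-identical reproducibility under a fixed seed
  expect_identical(small_worldness(lat, n_random = 10, seed = 3)$sigma,
                   small_worldness(lat, n_random = 10, seed = 3)$sigma)
})

test_that("compute_metrics bundles parts consistently and handles K5", {
  m <- compute_metrics(make_complete_graph(5), n_random = 5, seed = 1)
  expect_equal(m$lp, 1)
  expect_equal(m$eglob, 1)
  expect_equal(m$cp, 1)
  expect_equal(m$elocal, 1)
  td <- tidy(m)
  expect_equal(td$metric, c("lp", "eglob", "cp", "elocal", "sigma"))
  expect_equal(td$value[1:4], rep(1, 4))
  # node profiles agree with direct per-node computation
  A <- make_ring_lattice(12, 4)
  m2 <- compute_metrics(A, n_random = 5, seed = 2)
  expect_equal(m2$node_profiles$degree, rep(4L, 12))
  expect_equal(m2$node_profiles$betweenness,
               unname(betweenness_centrality(A)))
  expect_equal(mean(m2$node_profiles$local_efficiency), m2$elocal)
})

test_that("ROI betweenness extraction maps flags to node values and names missing ROIs", {
  atlas <- tiny_atlas(8)
  # left hemisphere star centred on the mfog node (label 1)
  A <- make_star_graph(8)
  net <- hemilat:::new_hemisphere_network("left", 1:8, A)
  # a star has zero clustering, so sigma is undefined (classed warning)
  expect_warning(m <- compute_metrics(net, n_random = 5, seed = 1),
                 class = "hemilat_undefined_metric")
  expect_warning(roi <- extract_roi_betweenness(m, atlas), NA)
  expect_equal(roi$betweenness[roi$roi == "mfog"], 1)
  expect_equal(roi$betweenness,
               m$node_profiles$betweenness[match(1:4, m$node_profiles$label_id)])
  bad_atlas <- atlas
  bad_atlas$roi_flag[bad_atlas$roi_flag == "stg"] <- "none"
  expect_error(extract_roi_betweenness(m, bad_atlas),
               regexp = "stg", class = "hemilat_input_error")
})

test_that("disconnected graphs get a component note and a largest-component sigma", {
  A <- matrix(0L, 7, 7)
  A[1:5, 1:5] <- make_cycle_graph(5)
  A[6, 7] <- A[7, 6] <- 1L
  # the 5-cycle component is triangle-free, so sigma itself is undefined
  expect_warning(sw <- small_worldness(A, n_random = 5, seed = 4),
                 class = "hemilat_undefined_metric")
  expect_match(sw$component_note, "5 of 7")
  expect_equal(sw$lp, 1.5)
})
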