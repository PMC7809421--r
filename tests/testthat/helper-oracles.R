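# Independent brute-force oracles. These deliberately share no code with the
# package internals: distances via Floyd-Warshall, betweenness via explicit
# geodesic enumeration, Fisher via hypergeometric table enumeration.

oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_components <- function(A) {
  D <- oracle_floyd_warshall(A)
  comp <- integer(nrow(A))
  cur <- 0L
  for (i in seq_len(nrow(A))) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[is.finite(D[i, ])] <- cur
    }
  }
  comp
}

oracle_lp <- function(A) {
  comp <- oracle_components(A)
  big <- which(comp == which.max(tabulate(comp)))
  if (length(big) < 2) return(NA_real_)
  D <- oracle_floyd_warshall(A)[big, big, drop = FALSE]
  vals <- D[row(D) != col(D)]
  mean(vals)
}

oracle_eglob <- function(A) {
  D <- oracle_floyd_warshall(A)
  n <- nrow(A)
  if (n < 2) return(0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
  }
  s / (n * (n - 1))
}

oracle_cp <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (A[nb[a], nb[b]] > 0) e <- e + 1
    }
    cc[i] <- 2 * e / (k * (k - 1))
  }
  mean(cc)
}

oracle_elocal <- function(A) {
  n <- nrow(A)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    le[i] <- oracle_eglob(A[nb, nb, drop = FALSE])
  }
  mean(le)
}

# all geodesics between s and t, as lists of vertex sequences
oracle_geodesics <- function(A, s, t, D = oracle_floyd_warshall(A)) {
  if (s == t) return(list(s))
  if (!is.finite(D[s, t])) return(list())
  paths <- list()
  for (u in which(A[s, ] > 0)) {
    if (D[u, t] == D[s, t] - 1) {
      for (p in oracle_geodesics(A, u, t, D)) {
        paths[[length(paths) + 1]] <- c(s, p)
      }
    }
  }
  paths
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_floyd_warshall(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_geodesics(A, s, t, D)
    if (length(paths) == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      b[v] <- b[v] + through / length(paths)
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# Two-sided Fisher p by enumerating all tables with the observed margins.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  point_p <- function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }
  xs <- max(0, r1 - (n - c1)):min(r1, c1)
  probs <- vapply(xs, point_p, numeric(1))
  obs <- point_p(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# every connected simple graph on n nodes, as adjacency matrices
all_connected_graphs <- function(n) {
  n_pairs <- n * (n - 1) / 2
  out <- list()
  for (code in 0:(2^n_pairs - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n_pairs)]
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- bits
    A <- A + t(A)
    if (all(oracle_components(A) == 1L)) out[[length(out) + 1]] <- A
  }
  out
}

make_path_graph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}

make_complete_graph <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}

make_cycle_graph <- function(n) {
  A <- make_path_graph(n)
  A[1, n] <- A[n, 1] <- 1L
  A
}

make_star_graph <- function(n) {
  A <- matrix(0L, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1L
  A
}

# ring lattice on n nodes with k neighbours (k even)
make_ring_lattice <- function(n, k) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i - 1 + s) %% n) + 1
    A[i, j] <- A[j, i] <- 1L
  }
  A
}

tiny_atlas <- function(n_per_hemisphere = 8L) neonatal_atlas(n_per_hemisphere)
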