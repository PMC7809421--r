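#' Mean fractional anisotropy of one fiber
#'
#' A fiber's FA is the arithmetic mean of the FA values of the voxels it
#' traverses.
#'
#' @param voxel_fa Numeric vector of per-voxel FA values in `[0, 1]`.
#' @return A single FA value.
#' @examples
#' fiber_mean_fa(c(0.2, 0.4))
#' @export
fiber_mean_fa <- function(voxel_fa) {
  if (length(voxel_fa) == 0) {
    abort("A fiber must have at least one voxel FA value.",
          class = "hemilat_input_error")
  }
  if (any(!is.finite(voxel_fa)) || any(voxel_fa < 0) || any(voxel_fa > 1)) {
    abort("Voxel FA values must be finite and in [0, 1].",
          class = "hemilat_input_error")
  }
  mean(voxel_fa)
}

#' Mean FA of the tract connecting one region pair
#'
#' Two-stage average: FA is first averaged over the voxels of each fiber, then
#' averaged over the fibers of the tract. Every fiber carries equal weight
#' regardless of how many voxels it spans.
#'
#' @param fibers List of numeric vectors, one per fiber, each holding that
#'   fiber's voxel FA values.
#' @return The tract-mean FA, or `NA_real_` when the pair has no fibers (an
#'   absent edge, not an error).
#' @examples
#' tract_mean_fa(list(c(0.2, 0.4), 0.6))
#' @export
tract_mean_fa <- function(fibers) {
  if (length(fibers) == 0) return(NA_real_)
  mean(vapply(fibers, fiber_mean_fa, numeric(1)))
}

new_connectome <- function(subject_id, labels, fa_weight, fiber_count,
                           min_fibers = 1L) {
  binary <- (fiber_count >= min_fibers) * 1L
  structure(
    list(subject_id = subject_id,
         labels = as.integer(labels),
         fa_weight = fa_weight,
         fiber_count = fiber_count,
         binary = binary,
         min_fibers = as.integer(min_fibers)),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject %s: %d nodes, %d edges (min_fibers = %d)\n",
              x$subject_id, length(x$labels), sum(x$binary) / 2, x$min_fibers))
  invisible(x)
}

#' Build a connectivity matrix from streamline summaries
#'
#' Aggregates per-fiber endpoint labels and voxel FA samples into symmetric
#' region-by-region matrices: a fiber count, a tract-mean FA weight (the
#' two-stage average of [tract_mean_fa()]), and a binary adjacency obtained by
#' thresholding the count at `min_fibers`. Self-loop fibers (both endpoints in
#' the same region) are dropped with an informative message, since all network
#' measures here are defined on simple graphs.
#'
#' @param streamlines A streamline summary tibble with columns `subject_id`,
#'   `label_a`, `label_b` (integer atlas labels) and `voxel_fa` (list-column of
#'   numeric vectors, one element per fiber).
#' @param atlas Atlas label table, see [neonatal_atlas()].
#' @param min_fibers Minimum streamline count for an edge to be present in the
#'   binary view (default 1, the most permissive rule).
#' @return A `connectome` object holding `labels`, `fa_weight`, `fiber_count`
#'   and `binary` matrices (all symmetric, zero diagonal).
#' @export
build_matrix <- function(streamlines, atlas, min_fibers = 1L) {
  validate_atlas(atlas)
  labels <- atlas$label_id
  n <- length(labels)
  subject_id <- if (nrow(streamlines) > 0) streamlines$subject_id[[1]] else NA_character_

  unknown <- setdiff(unique(c(streamlines$label_a, streamlines$label_b)), labels)
  if (length(unknown) > 0) {
    abort(paste0("Streamline endpoint label(s) not in atlas: ",
                 paste(sort(unknown), collapse = ", ")),
          class = "hemilat_input_error")
  }

  idx <- function(l) match(l, labels)
  fiber_count <- matrix(0L, n, n, dimnames = list(labels, labels))
  fa_sum <- matrix(0, n, n)

  loops <- 0L
  if (nrow(streamlines) > 0) {
    for (f in seq_len(nrow(streamlines))) {
      a <- idx(streamlines$label_a[[f]])
      b <- idx(streamlines$label_b[[f]])
      if (a == b) {
        loops <- loops + 1L
        next
      }
      fa <- fiber_mean_fa(streamlines$voxel_fa[[f]])
      fiber_count[a, b] <- fiber_count[a, b] + 1L
      fiber_count[b, a] <- fiber_count[b, a] + 1L
      fa_sum[a, b] <- fa_sum[a, b] + fa
      fa_sum[b, a] <- fa_sum[b, a] + fa
    }
  }
  if (loops > 0) {
    inform(sprintf("build_matrix: dropped %d self-loop fiber(s).", loops))
  }
  fa_weight <- matrix(0, n, n, dimnames = list(labels, labels))
  has <- fiber_count > 0
  fa_weight[has] <- fa_sum[has] / fiber_count[has]
  new_connectome(subject_id, labels, fa_weight, fiber_count, min_fibers)
}

#' Re-threshold the binary view of a connectome
#'
#' @param connectome A `connectome` object.
#' @param min_fibers Minimum fiber count for an edge (>= 1).
#' @return The connectome with its `binary` matrix recomputed.
#' @export
binarize <- function(connectome, min_fibers = 1L) {
  if (min_fibers < 1) {
    abort("`min_fibers` must be >= 1.", class = "hemilat_config_error")
  }
  connectome$min_fibers <- as.integer(min_fibers)
  connectome$binary <- (connectome$fiber_count >= min_fibers) * 1L
  connectome
}

new_hemisphere_network <- function(side, labels, adjacency) {
  labels <- as.integer(labels)
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(labels, labels)
  structure(list(side = side, labels = labels, adjacency = adjacency),
            class = "hemisphere_network")
}

#' @export
print.hemisphere_network <- function(x, ...) {
  cat(sprintf("<hemisphere_network> %s: %d nodes, %d edges\n",
              x$side, length(x$labels), sum(x$adjacency) / 2))
  invisible(x)
}

#' Split a connectome into intra-hemispheric binary networks
#'
#' Takes the induced subgraph of the binary connectome on each hemisphere's
#' labels. Interhemispheric edges and midline labels are excluded; their
#' counts are reported with a message so the information loss is visible.
#'
#' @param connectome A `connectome` object.
#' @param atlas Atlas label table with a `hemisphere` column.
#' @param quiet Suppress the interhemispheric-edge message.
#' @return A named list with `left` and `right` `hemisphere_network` objects.
#' @export
split_hemispheres <- function(connectome, atlas, quiet = FALSE) {
  validate_atlas(atlas)
  atlas <- atlas[match(connectome$labels, atlas$label_id), ]
  if (anyNA(atlas$label_id)) {
    abort("Connectome labels missing from atlas.", class = "hemilat_input_error")
  }
  out <- list()
  for (side in c("left", "right")) {
    keep <- which(atlas$hemisphere == side)
    if (length(keep) < 2) {
      abort(sprintf("Hemisphere '%s' has fewer than 2 nodes.", side),
            class = "hemilat_input_error")
    }
    out[[side]] <- new_hemisphere_network(
      side, connectome$labels[keep], connectome$binary[keep, keep, drop = FALSE])
  }
  total_edges <- sum(connectome$binary) / 2
  intra_edges <- sum(out$left$adjacency) / 2 + sum(out$right$adjacency) / 2
  dropped <- total_edges - intra_edges
  if (!quiet && dropped > 0) {
    inform(sprintf(
      "split_hemispheres: excluded %d interhemispheric/midline edge(s).", dropped))
  }
  out
}

as_igraph <- function(network) {
  igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected")
}
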