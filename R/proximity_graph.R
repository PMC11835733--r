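# Nearest-neighbour proximity graph --------------------------------------

#' Sample-size-dependent neighbour count
#'
#' The number of nearest neighbours grows with the base-10 log of the
#' cohort size, `nn = max(10, 10 + 15 * (log10(N) - 4))`, rounded to the
#' nearest integer and floored at 10.
#'
#' @param n_total Number of individuals (>= 2).
#' @return Integer neighbour count.
#' @export
neighbor_count <- function(n_total) {
  stopifnot(n_total >= 2)
  as.integer(max(10, round(10 + 15 * (log10(n_total) - 4))))
}

#' Build the binary k-nearest-neighbour graph
#'
#' k nearest neighbours in Euclidean residual space, symmetrized by union,
#' with every edge weight set to 1. The search is an exact kd-tree lookup,
#' so the graph is deterministic for given inputs.
#'
#' @param residuals `residual_matrix` or numeric matrix.
#' @param nn Neighbour count; defaults to [neighbor_count()] of the sample
#'   size.
#' @return An [igraph::graph] with graph attribute `nn_used`.
#' @export
build_graph <- function(residuals, nn = NULL) {
  x <- if (inherits(residuals, "residual_matrix")) residuals$values else residuals
  n <- nrow(x)
  if (is.null(nn)) nn <- neighbor_count(n)
  if (nn >= n) stop("nn must be smaller than the number of individuals")
  knn <- RANN::nn2(x, k = nn + 1L)$nn.idx
  from <- rep(seq_len(n), each = nn)
  to <- as.vector(t(knn[, -1L, drop = FALSE]))
  # self can appear in a later column when points are duplicated
  keep <- from != to
  g <- igraph::graph_from_edgelist(cbind(from, to)[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  g <- igraph::simplify(g)
  igraph::E(g)$weight <- 1
  g$nn_used <- as.integer(nn)
  g
}

#' Two-dimensional embedding for visual inspection
#'
#' A UMAP layout of the residual space with the same neighbour count and
#' binary edge weights as the clustering graph (density-scaled when the
#' installed backend supports it). The embedding is for figures only; no
#' inference in the package uses the coordinates.
#'
#' @param residuals `residual_matrix` or matrix.
#' @param nn Neighbour count (defaults as in [build_graph()]).
#' @param seed Integer seed; identical inputs and seed give identical
#'   coordinates.
#' @return N x 2 coordinate matrix.
#' @export
embed_2d <- function(residuals, nn = NULL, seed = 1L) {
  x <- if (inherits(residuals, "residual_matrix")) residuals$values else residuals
  if (is.null(nn)) nn <- neighbor_count(nrow(x))
  if (!requireNamespace("uwot", quietly = TRUE))
    stop("the 'uwot' package is required for embed_2d()")
  args <- list(X = x, n_neighbors = nn, n_components = 2L,
               n_threads = 1L, n_sgd_threads = 0L)
  extra <- c(binary_edge_weights = TRUE, dens_scale = 1)
  ok <- intersect(names(extra), names(formals(uwot::umap)))
  args[ok] <- extra[ok]
  set.seed(seed)
  coords <- do.call(uwot::umap, args)
  colnames(coords) <- c("umap1", "umap2")
  coords
}
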