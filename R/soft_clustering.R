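# Graph communities -> fixed-moment Gaussian mixture ---------------------
#
# Hard Leiden communities on the proximity graph are converted into
# Gaussian components via eigenvector-centrality-weighted moments; a
# concordant reference component (zero mean, identity covariance) is
# always present, and only the component weights are fitted by EM. The
# result is a per-individual probability over profiles.

#' Initial partition from the leading-eigenvector method
#'
#' @param graph Proximity graph ([build_graph()]).
#' @return A `hard_partition`: list with `membership` (contiguous integer
#'   labels) and `modularity`.
#' @export
seed_partition <- function(graph) {
  stopifnot(igraph::vcount(graph) > 0)
  cl <- igraph::cluster_leading_eigen(graph)
  structure(
    list(membership = as.integer(igraph::membership(cl)),
         modularity = igraph::modularity(graph, igraph::membership(cl))),
    class = "hard_partition"
  )
}

#' Best-of-restarts Leiden partition
#'
#' Runs the Leiden modularity algorithm `n_iter` times from the seed
#' partition under varying random streams and keeps the partition with the
#' highest modularity. Leiden guarantees that every returned community
#' induces a connected subgraph.
#'
#' @param graph Proximity graph.
#' @param seeds Optional `hard_partition` used as the initial membership
#'   (typically [seed_partition()]).
#' @param n_iter Number of restarts (default 500).
#' @param seed Integer seed controlling the restart streams.
#' @return A `hard_partition`.
#' @export
leiden_consensus <- function(graph, seeds = NULL, n_iter = 500L, seed = 1L) {
  init <- if (!is.null(seeds)) seeds$membership else NULL
  if (!is.null(init) && length(init) != igraph::vcount(graph))
    stop("seed partition does not cover the graph")
  best <- NULL
  best_q <- -Inf
  set.seed(seed)
  for (i in seq_len(n_iter)) {
    cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 initial_membership = init,
                                 n_iterations = 5L)
    memb <- as.integer(igraph::membership(cl))
    q <- igraph::modularity(graph, memb)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  # relabel contiguously by decreasing community size
  sizes <- sort(table(best), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  structure(list(membership = as.integer(relab[as.character(best)]),
                 modularity = best_q),
            class = "hard_partition")
}

#' Within-community eigenvector centrality weights
#'
#' Eigenvector centrality computed on each community's induced subgraph and
#' normalized so the most central member has weight 1. Singleton
#' communities get weight 1.
#'
#' @param graph Proximity graph.
#' @param partition `hard_partition` covering all nodes.
#' @return Numeric vector of per-node weights in (0, 1].
#' @export
centrality_weights <- function(graph, partition) {
  memb <- partition$membership
  stopifnot(length(memb) == igraph::vcount(graph))
  w <- numeric(length(memb))
  for (k in unique(memb)) {
    idx <- which(memb == k)
    if (length(idx) == 1L) {
      w[idx] <- 1
      next
    }
    sub <- igraph::induced_subgraph(graph, idx)
    ec <- igraph::eigen_centrality(sub)$vector  # scaled so max is 1
    ec[ec <= 0] <- min(ec[ec > 0], 1) * 1e-8  # isolated members keep tiny mass
    w[idx] <- ec
  }
  w
}

.wmoments <- function(x, w) {
  sw <- sum(w)
  mu <- colSums(x * w) / sw
  xc <- sweep(x, 2L, mu)
  sigma <- crossprod(xc * w, xc) / sw
  list(mean = mu, cov = sigma)
}

.name_component <- function(mu) {
  j <- which.max(abs(mu))
  sprintf("d_%s_%s", names(mu)[j] %||% paste0("v", j),
          if (mu[j] >= 0) "high" else "low")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct the fixed-moment Gaussian mixture from a partition
#'
#' Each sufficiently large community contributes a component whose mean and
#' covariance are the centrality-weighted moments of its members'
#' residuals. One concordant component with zero mean and identity
#' covariance is always included; communities smaller than
#' `min_size` (default 10 x number of biomarkers) are not promoted to
#' components and their members count toward the concordant initial
#' weight. Initial weights are proportional to member counts.
#'
#' Components are named after the biomarker with the largest absolute mean
#' residual and its direction (e.g. `d_tg_high`); name clashes get a
#' numeric suffix.
#'
#' @param residuals `residual_matrix` or matrix.
#' @param partition `hard_partition`.
#' @param weights Per-node weights from [centrality_weights()]; uniform if
#'   `NULL`.
#' @param min_size Minimum community size promoted to a component.
#' @param ridge Ridge added to near-singular covariances.
#' @return A `mixture_model`: list with `labels`, `means` (K x p),
#'   `covs` (list of K), `weights` (K, summing to 1), `concordant`
#'   (label of the reference component).
#' @export
build_mixture <- function(residuals, partition, weights = NULL,
                          min_size = NULL, ridge = 1e-6) {
  x <- if (inherits(residuals, "residual_matrix")) residuals$values else residuals
  p <- ncol(x)
  if (is.null(min_size)) min_size <- 10L * p
  memb <- partition$membership
  stopifnot(length(memb) == nrow(x))
  if (is.null(weights)) weights <- rep(1, nrow(x))

  labels <- character(0)
  means <- NULL
  covs <- list()
  counts <- numeric(0)
  absorbed <- 0
  for (k in sort(unique(memb))) {
    idx <- which(memb == k)
    if (length(idx) < min_size) {
      absorbed <- absorbed + length(idx)
      next
    }
    mm <- .wmoments(x[idx, , drop = FALSE], weights[idx])
    ev <- eigen(mm$cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) mm$cov <- mm$cov + ridge * diag(p)
    names(mm$mean) <- colnames(x)
    lab <- .name_component(mm$mean)
    if (lab %in% labels) lab <- paste0(lab, "_", sum(startsWith(labels, lab)) + 1L)
    labels <- c(labels, lab)
    means <- rbind(means, mm$mean)
    covs <- c(covs, list(mm$cov))
    counts <- c(counts, length(idx))
  }
  # concordant reference component, always present
  labels <- c(labels, "concordant")
  means <- rbind(means, rep(0, p))
  covs <- c(covs, list(diag(p)))
  counts <- c(counts, max(absorbed, 1))
  rownames(means) <- labels
  colnames(means) <- colnames(x)

  structure(
    list(labels = labels, means = means, covs = covs,
         weights = counts / sum(counts), concordant = "concordant",
         loglik = NA_real_),
    class = "mixture_model"
  )
}

# N x K matrix of component log-densities (moments are fixed, so this is
# computed once per dataset)
.component_logdens <- function(mixture, x) {
  ld <- vapply(seq_along(mixture$labels), function(k) {
    mvtnorm::dmvnorm(x, mean = mixture$means[k, ], sigma = mixture$covs[[k]],
                     log = TRUE)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) ld <- matrix(ld, nrow = 1L)
  colnames(ld) <- mixture$labels
  ld
}

.responsibilities <- function(logdens, weights) {
  lw <- sweep(logdens, 2L, log(weights), `+`)
  m <- apply(lw, 1L, max)
  if (any(!is.finite(m))) stop("all component densities are zero for some rows")
  num <- exp(lw - m)
  list(resp = num / rowSums(num), loglik = sum(m + log(rowSums(num))))
}

#' Fit mixture weights by EM with fixed moments
#'
#' Component means and covariances stay fixed; only the weights (the
#' population proportions of the profiles) are updated from the averaged
#' responsibilities until `max |delta pi| < tol` or `max_iter` iterations.
#' The log-likelihood is non-decreasing across iterations.
#'
#' @param mixture `mixture_model`.
#' @param residuals `residual_matrix` or matrix.
#' @param tol Convergence tolerance on the weight change (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return The mixture with fitted `weights`, final `loglik`, the
#'   iteration `loglik_trace`, and `degenerate` flags for weights below
#'   1e-6.
#' @export
fit_mixture_weights <- function(mixture, residuals, tol = 1e-8,
                                max_iter = 1000L) {
  x <- if (inherits(residuals, "residual_matrix")) residuals$values else residuals
  logdens <- .component_logdens(mixture, x)
  pi_k <- mixture$weights
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    rr <- .responsibilities(logdens, pi_k)
    trace <- c(trace, rr$loglik)
    pi_new <- colMeans(rr$resp)
    if (max(abs(pi_new - pi_k)) < tol) {
      pi_k <- pi_new
      break
    }
    pi_k <- pi_new
  }
  mixture$weights <- as.numeric(pi_k)
  mixture$loglik <- trace[length(trace)]
  mixture$loglik_trace <- trace
  mixture$degenerate <- mixture$weights < 1e-6
  mixture
}

#' Per-individual profile allocation probabilities
#'
#' Posterior responsibility of each component for each individual,
#' computed in log space with log-sum-exp stabilization. Rows sum to 1.
#'
#' @param mixture Fitted `mixture_model`.
#' @param residuals `residual_matrix` or matrix.
#' @return N x K matrix with component labels as column names.
#' @export
allocate <- function(mixture, residuals) {
  x <- if (inherits(residuals, "residual_matrix")) residuals$values else residuals
  logdens <- .component_logdens(mixture, x)
  rr <- .responsibilities(logdens, mixture$weights)
  rr$resp
}

#' Relative-entropy separation index of an allocation
#'
#' `1 - (total allocation entropy) / (N * ln K)`: 1 for one-hot
#' allocations (complete separation), 0 when every individual has uniform
#' probabilities over the K profiles (indistinguishable profiles).
#'
#' @param alloc Allocation matrix (rows sum to 1).
#' @return Scalar in `[0, 1]`.
#' @export
separation_index <- function(alloc) {
  K <- ncol(alloc)
  if (K == 1L) {
    warning("separation index is undefined for a single profile; returning 1")
    return(1)
  }
  h <- alloc * log(alloc)
  h[alloc == 0] <- 0
  1 - sum(-h) / (nrow(alloc) * log(K))
}

#' Partition quality: separation index and per-profile transitivity
#'
#' The separation index summarizes how concentrated the allocation
#' probabilities are; transitivity (the global clustering coefficient of
#' the subgraph induced by each profile's maximum-probability members)
#' measures within-profile cohesion.
#'
#' @param alloc Allocation matrix.
#' @param graph Proximity graph on the same individuals.
#' @return List with `entropy` and named `transitivity` vector.
#' @export
partition_quality <- function(alloc, graph) {
  stopifnot(nrow(alloc) == igraph::vcount(graph))
  ent <- separation_index(alloc)
  hard <- colnames(alloc)[max.col(alloc, ties.method = "first")]
  tr <- vapply(unique(hard), function(lab) {
    idx <- which(hard == lab)
    igraph::transitivity(igraph::induced_subgraph(graph, idx), type = "global")
  }, numeric(1))
  list(entropy = ent, transitivity = tr)
}

#' Run the full profiling pipeline on a residual matrix
#'
#' Graph construction, leading-eigenvector seeding, best-of-restarts
#' Leiden, centrality-weighted mixture construction, weight-only EM and
#' allocation, in one call.
#'
#' @param residuals `residual_matrix` or matrix.
#' @param nn Neighbour count (defaults to [neighbor_count()]).
#' @param n_iter Leiden restarts.
#' @param seed Integer seed for the restart streams.
#' @param min_size Minimum community size promoted to a component.
#' @return List with `graph`, `partition`, `mixture`, `alloc`, `quality`.
#' @export
fit_profiles <- function(residuals, nn = NULL, n_iter = 500L, seed = 1L,
                         min_size = NULL) {
  graph <- build_graph(residuals, nn = nn)
  seeds <- seed_partition(graph)
  part <- leiden_consensus(graph, seeds, n_iter = n_iter, seed = seed)
  w <- centrality_weights(graph, part)
  mix <- build_mixture(residuals, part, w, min_size = min_size)
  mix <- fit_mixture_weights(mix, residuals)
  alloc <- allocate(mix, residuals)
  list(graph = graph, partition = part, mixture = mix, alloc = alloc,
       quality = partition_quality(alloc, graph))
}

#' Serialize / restore a mixture model as JSON
#'
#' @param mixture `mixture_model`.
#' @param path File path.
#' @return `read_mixture` returns a `mixture_model`.
#' @export
write_mixture <- function(mixture, path) {
  obj <- list(labels = mixture$labels, means = mixture$means,
              covs = mixture$covs, weights = mixture$weights,
              concordant = mixture$concordant, loglik = mixture$loglik)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mixture
#' @export
read_mixture <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- as.matrix(obj$means)
  rownames(means) <- obj$labels
  covs <- lapply(seq_along(obj$labels), function(k) as.matrix(obj$covs[[k]]))
  structure(
    list(labels = obj$labels, means = means, covs = covs,
         weights = obj$weights, concordant = obj$concordant,
         loglik = obj$loglik %||% NA_real_),
    class = "mixture_model"
  )
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: %d profiles (%s concordant)\n",
              length(x$labels), x$concordant))
  print(data.frame(label = x$labels, weight = round(x$weights, 4)))
  invisible(x)
}
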