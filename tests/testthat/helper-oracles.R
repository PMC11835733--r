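# Independent oracles used across test files.

# adjusted Rand index, brute-force contingency-table formula
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# exact kNN edge set by all-pairs distances, union-symmetrized
knn_edges_bruteforce <- function(x, nn) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  edges <- NULL
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(nn + 1)]
    edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

edge_set <- function(g) {
  e <- igraph::as_edgelist(g)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# tiny cohort with hand-controllable biomarkers; remaining biomarkers are
# filled with noise so required columns exist
make_mini_cohort <- function(n, seed = 1) {
  set.seed(seed)
  cohort <- data.frame(
    id = sprintf("m%03d", seq_len(n)),
    sex = "female",
    age = stats::runif(n, 40, 70),
    smoking = stats::rbinom(n, 1, 0.3),
    bmi = stats::runif(n, 20, 35)
  )
  for (b in biomarker_names()) cohort[[b]] <- stats::rnorm(n)
  cohort
}

# mixture_model constructed directly (bypasses graph clustering)
make_mixture <- function(means, covs, weights, labels,
                         concordant = "concordant") {
  rownames(means) <- labels
  structure(list(labels = labels, means = means, covs = covs,
                 weights = weights, concordant = concordant,
                 loglik = NA_real_),
            class = "mixture_model")
}
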