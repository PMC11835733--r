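make_two_cliques <- function(m = 10) {
  g1 <- igraph::make_full_graph(m)
  g2 <- igraph::make_full_graph(m)
  igraph::disjoint_union(g1, g2)
}

test_that("leading-eigenvector seeding recovers obvious structure", {
  g <- make_two_cliques(10)
  sp <- seed_partition(g)
  expect_equal(length(unique(sp$membership)), 2L)
  expect_equal(length(unique(sp$membership[1:10])), 1L)
  expect_equal(length(unique(sp$membership[11:20])), 1L)

  single <- igraph::make_full_graph(8)
  expect_equal(length(unique(seed_partition(single)$membership)), 1L)
})

test_that("Leiden consensus recovers planted blobs with connected communities", {
  set.seed(41)
  blobs <- rbind(
    matrix(stats::rnorm(60 * 10), 60, 10),
    sweep(matrix(stats::rnorm(60 * 10), 60, 10), 2, c(8, rep(0, 9)), `+`),
    sweep(matrix(stats::rnorm(60 * 10), 60, 10), 2, c(0, 8, rep(0, 8)), `+`)
  )
  truth <- rep(1:3, each = 60)
  g <- build_graph(blobs, nn = 8)
  part <- leiden_consensus(g, seed_partition(g), n_iter = 20, seed = 2)
  expect_equal(ari_oracle(truth, part$membership), 1)
  for (k in unique(part$membership)) {
    sub <- igraph::induced_subgraph(g, which(part$membership == k))
    expect_equal(igraph::components(sub)$no, 1L)
  }

  # unique optimum: one restart equals many
  g2 <- make_two_cliques(8)
  p1 <- leiden_consensus(g2, n_iter = 1, seed = 1)
  p500 <- leiden_consensus(g2, n_iter = 50, seed = 9)
  expect_equal(p1$membership, p500$membership)
  expect_gte(p1$modularity, 0.3)
})

test_that("centrality weights are 1 on cliques and hub-dominant on stars", {
  m <- 12
  g <- make_two_cliques(m)
  part <- structure(list(membership = rep(1:2, each = m)),
                    class = "hard_partition")
  w <- centrality_weights(g, part)
  expect_equal(w, rep(1, 2 * m))

  star <- igraph::make_star(9, mode = "undirected", center = 1)
  pstar <- structure(list(membership = rep(1L, 9)), class = "hard_partition")
  ws <- centrality_weights(star, pstar)
  expect_equal(ws[1], 1)
  expect_true(all(ws[-1] < 1))
  expect_equal(stats::sd(ws[-1]), 0, tolerance = 1e-10)
  # eigenvector of a star: leaves are hub / sqrt(#leaves)
  expect_equal(unique(round(ws[-1], 8)), round(1 / sqrt(8), 8))
  expect_true(all(ws > 0 & ws <= 1))
})

test_that("mixture construction matches weighted-moment formulas", {
  x <- matrix(c(1.0, 2.0,
                2.0, 1.0,
                0.5, 0.5,
                3.0, 4.0,
                2.5, 0.0), 5, 2, byrow = TRUE,
              dimnames = list(NULL, c("fg", "hdl")))
  w <- c(0.2, 0.5, 1.0, 0.3, 0.8)
  part <- structure(list(membership = rep(1L, 5)), class = "hard_partition")
  mix <- build_mixture(x, part, weights = w, min_size = 1)

  mu <- colSums(x * w) / sum(w)
  sigma <- matrix(0, 2, 2)
  for (i in 1:5) sigma <- sigma + w[i] * tcrossprod(x[i, ] - mu)
  sigma <- sigma / sum(w)
  k <- which(mix$labels != "concordant")
  expect_equal(unname(mix$means[k, ]), unname(mu), tolerance = 1e-10)
  expect_equal(unname(mix$covs[[k]]), unname(sigma), tolerance = 1e-6)

  # exactly one concordant component with fixed moments
  expect_equal(sum(mix$labels == "concordant"), 1L)
  kc <- which(mix$labels == "concordant")
  expect_equal(unname(mix$means[kc, ]), c(0, 0))
  expect_equal(mix$covs[[kc]], diag(2))

  # uniform node weights degenerate to the plain community mean
  mix_u <- build_mixture(x, part, weights = rep(1, 5), min_size = 1)
  expect_equal(unname(mix_u$means[which(mix_u$labels != "concordant"), ]),
               unname(colMeans(x)), tolerance = 1e-12)
})

test_that("EM weight fitting recovers proportions and is monotone", {
  set.seed(43)
  p <- 4
  mu2 <- c(4, 4, 0, 0)
  n <- 4000
  z <- stats::rbinom(n, 1, 0.3)
  x <- matrix(stats::rnorm(n * p), n, p)
  x[z == 1, ] <- sweep(x[z == 1, , drop = FALSE], 2, mu2, `+`)
  mix <- make_mixture(rbind(rep(0, p), mu2),
                      list(diag(p), diag(p)),
                      c(0.5, 0.5), c("concordant", "d_up"))
  fit <- fit_mixture_weights(mix, x)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(fit$weights[2] - mean(z)), 3 * se)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))

  # K = 1 keeps weight 1
  m1 <- make_mixture(matrix(0, 1, p), list(diag(p)), 1, "concordant")
  expect_equal(fit_mixture_weights(m1, x)$weights, 1)
})

test_that("allocation is a proper posterior", {
  set.seed(44)
  x <- matrix(stats::rnorm(200 * 3), 200, 3)
  # two identical components: rows allocate to the weight ratio
  mix <- make_mixture(matrix(0, 2, 3), list(diag(3), diag(3)),
                      c(0.3, 0.7), c("a", "concordant"))
  al <- allocate(mix, x)
  expect_true(all(abs(rowSums(al) - 1) < 1e-8))
  expect_true(all(abs(al[, "a"] - 0.3) < 1e-10))

  # 1-D closed-form posterior
  m1 <- 0; m2 <- 2; s1 <- 1; s2 <- 0.5; w1 <- 0.4
  mix1 <- make_mixture(matrix(c(m1, m2), 2, 1),
                       list(matrix(s1^2), matrix(s2^2)),
                       c(w1, 1 - w1), c("concordant", "d"))
  xs <- matrix(seq(-3, 4, length.out = 30), ncol = 1)
  al1 <- allocate(mix1, xs)
  post <- w1 * stats::dnorm(xs[, 1], m1, s1) /
    (w1 * stats::dnorm(xs[, 1], m1, s1) +
       (1 - w1) * stats::dnorm(xs[, 1], m2, s2))
  expect_equal(al1[, "concordant"], post, tolerance = 1e-12)
})

test_that("separation index has the documented boundary behaviour", {
  onehot <- diag(5)[sample.int(5, 40, replace = TRUE), ]
  expect_equal(separation_index(onehot), 1)
  uniform <- matrix(1 / 4, 30, 4)
  expect_equal(separation_index(uniform), 0)

  a <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  h1 <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(separation_index(a), 1 - (h1 + log(2)) / (2 * log(2)),
               tolerance = 1e-12)

  # invariant under profile relabeling
  perm <- a[, c(2, 1)]
  expect_equal(separation_index(perm), separation_index(a))
  expect_warning(separation_index(matrix(1, 5, 1)), "single")
})

test_that("partition quality reports per-profile transitivity", {
  g <- make_two_cliques(6)
  alloc <- cbind(c(rep(0.95, 6), rep(0.05, 6)),
                 c(rep(0.05, 6), rep(0.95, 6)))
  colnames(alloc) <- c("a", "b")
  q <- partition_quality(alloc, g)
  expect_equal(unname(q$transitivity), c(1, 1))  # cliques are fully transitive
  expect_gt(q$entropy, 0.5)
})
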