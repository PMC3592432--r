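test_that("shrinkage endpoints recover the diagonal target and the sample covariance", {
  d <- random_expr(letters[1:5], n_per_class = 6, seed = 3)
  x <- d$x
  S <- cov(t(x))
  s1 <- shrink_covariance(x, lambda = 1)
  expect_equal(s1$sigma, diag(diag(S)), ignore_attr = TRUE)
  s0 <- shrink_covariance(x, lambda = 0)
  expect_equal(s0$sigma, S, ignore_attr = TRUE)
})

test_that("analytic shrinkage intensity matches a loop-based oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(8 * 12), 8, 12, dimnames = list(letters[1:8], NULL))
    est <- shrink_covariance(x)
    expect_equal(est$lambda, oracle_shrink_lambda(x), tolerance = 1e-10)
    lam <- est$lambda
    S <- cov(t(x))
    expect_equal(est$sigma, (1 - lam) * S + lam * diag(diag(S)),
                 ignore_attr = TRUE)
  }
})

test_that("shrunken covariance is positive definite when P exceeds n", {
  set.seed(9)
  for (p_over_n in list(c(50, 10), c(25, 5), c(15, 3))) {
    x <- matrix(rnorm(p_over_n[1] * p_over_n[2]), p_over_n[1],
                dimnames = list(sprintf("g%02d", 1:p_over_n[1]), NULL))
    est <- shrink_covariance(x)
    ev <- eigen(est$sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_gt(est$lambda, 0)
  }
  expect_error(shrink_covariance(matrix(1, 3, 4,
                                        dimnames = list(letters[1:3], NULL))),
               "zero-variance")
})

test_that("IPS on a complete graph reproduces S; on an empty graph, its diagonal", {
  genes <- letters[1:4]
  S <- random_cov(genes, seed = 5)
  complete <- igraph::make_full_graph(4)
  igraph::V(complete)$name <- genes
  fit <- ips_fit(S, complete, tol = 1e-10)
  expect_equal(fit$sigma, S, tolerance = 1e-8)

  empty <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(4, name = genes)
  fit0 <- ips_fit(S, empty, tol = 1e-10)
  expect_equal(fit0$sigma, diag(diag(S)), ignore_attr = TRUE)
  expect_equal(fit0$concentration, diag(1 / diag(S)), ignore_attr = TRUE)
})

test_that("IPS matches the 3-node decomposable closed form", {
  genes <- c("a", "b", "c")
  S <- random_cov(genes, seed = 7)
  chain <- ugraph(c("a", "b", "b", "c"))
  fit <- ips_fit(S, chain, tol = 1e-12)
  expect_equal(fit$sigma["a", "c"], S["a", "b"] * S["b", "c"] / S["b", "b"],
               tolerance = 1e-8)
  expect_equal(fit$concentration["a", "c"], 0)
  n <- 30
  jt <- junction_tree(chain)
  expect_equal(ggm_loglik(fit, S, n), oracle_decomposable_loglik(S, jt, n),
               tolerance = 1e-8)
})

test_that("IPS equals the clique/separator closed-form MLE on random decomposable graphs", {
  for (seed in 1:15) {
    g <- random_decomposable(8, seed)
    genes <- sort(igraph::V(g)$name)
    S <- random_cov(genes, seed = seed + 100)
    fit <- ips_fit(S, g, tol = 1e-12, trace_loglik = TRUE)
    jt <- junction_tree(g)
    orc <- oracle_decomposable_mle(S, jt)
    expect_lt(max(abs(fit$sigma - orc$sigma)), 1e-6)
    expect_lt(max(abs(fit$concentration - orc$concentration)), 1e-6)
    # invariants: exact zeros off the graph, clique blocks match S
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)[genes, genes] > 0
    off <- fit$concentration
    off[A | diag(length(genes)) > 0] <- 0
    expect_equal(max(abs(off)), 0)
    for (cl in jt$cliques) {
      idx <- match(cl, genes)
      expect_lt(max(abs(fit$sigma[idx, idx] - S[idx, idx])), 1e-7)
    }
    # likelihood kernel is non-decreasing across sweeps
    tr <- fit$loglik_trace
    if (length(tr) > 1)
      expect_true(all(diff(tr) > -1e-9))
  }
})

test_that("constrained fits never beat the saturated likelihood", {
  genes <- letters[1:5]
  S <- random_cov(genes, seed = 11)
  n <- 40
  complete <- igraph::make_full_graph(5)
  igraph::V(complete)$name <- genes
  sat <- ggm_loglik(ips_fit(S, complete), S, n)
  expect_equal(sat, (n / 2) * (-as.numeric(determinant(S)$modulus) - 5),
               tolerance = 1e-6)
  for (seed in 1:5) {
    g <- random_decomposable(5, seed)
    sub_genes <- sort(igraph::V(g)$name)
    Ssub <- S[sub_genes, sub_genes]
    satsub <- -(length(sub_genes) +
                  as.numeric(determinant(Ssub)$modulus)) * n / 2
    ll <- ggm_loglik(ips_fit(Ssub, g), Ssub, n)
    expect_lte(ll, satsub + 1e-8)
  }
})
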