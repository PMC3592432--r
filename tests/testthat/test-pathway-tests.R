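make_chain_data <- function(seed = 1, n = 8, shift = 0) {
  set.seed(seed)
  genes <- c("a", "b", "c")
  x <- matrix(rnorm(3 * 2 * n), 3, dimnames = list(genes, NULL))
  x[, seq(n + 1, 2 * n)] <- x[, seq(n + 1, 2 * n)] + shift
  list(data = expression_dataset(x, rep(c("A", "B"), each = n)),
       graph = ugraph(c("a", "b", "b", "c")))
}

test_that("permutation p-values obey the add-one rule and B granularity", {
  f <- make_chain_data()
  res <- concentration_test(f$data, f$graph, B = 19, seed = 5)
  expect_gte(res$p_value, 1 / 20)
  expect_lte(res$p_value, 1)
  expect_equal(res$p_value * 20, round(res$p_value * 20))  # multiples of 1/20

  resm <- mean_test(f$data, f$graph, B = 19, seed = 5)
  expect_equal(resm$p_value * 20, round(resm$p_value * 20))
  expect_error(concentration_test(f$data, f$graph, B = 5), "at least 19")
})

test_that("statistics are invariant to swapping the class labels", {
  f <- make_chain_data(seed = 2)
  swapped <- expression_dataset(
    f$data$x, factor(f$data$classes, levels = rev(levels(f$data$classes))))
  for (fun in list(
    function(d) concentration_test(d, f$graph, B = 19, seed = 1)$statistic,
    function(d) mean_test(d, f$graph, TRUE, B = 19, seed = 1)$statistic,
    function(d) mean_test(d, f$graph, FALSE, B = 19, seed = 1)$statistic)) {
    expect_equal(fun(f$data), fun(swapped), tolerance = 1e-10)
  }
})

test_that("identical seeds give bit-identical p-values; different seeds may differ", {
  f <- make_chain_data(seed = 3)
  a <- concentration_test(f$data, f$graph, B = 99, seed = 7)
  b <- concentration_test(f$data, f$graph, B = 99, seed = 7)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$statistic, b$statistic)
})

test_that("a uniform mean shift never decreases the mean-test statistic", {
  # fixed noise with equal class means, then a pure shift added to class B
  set.seed(4)
  genes <- c("a", "b", "c")
  noise <- matrix(rnorm(3 * 20), 3, dimnames = list(genes, NULL))
  noise[, 1:10] <- noise[, 1:10] - rowMeans(noise[, 1:10])
  noise[, 11:20] <- noise[, 11:20] - rowMeans(noise[, 11:20])
  graph <- ugraph(c("a", "b", "b", "c"))
  stats_homo <- numeric(0)
  stats_het <- numeric(0)
  for (shift in 0:5) {
    x <- noise
    x[, 11:20] <- x[, 11:20] + shift
    d <- expression_dataset(x, rep(c("A", "B"), each = 10))
    stats_homo <- c(stats_homo,
                    mean_test(d, graph, TRUE, B = 19, seed = 1)$statistic)
    stats_het <- c(stats_het,
                   mean_test(d, graph, FALSE, B = 19, seed = 1)$statistic)
  }
  expect_true(all(diff(stats_homo) > 0))
  expect_true(all(diff(stats_het) > 0))
})

test_that("a strong shift attains the minimum possible p-value", {
  f <- make_chain_data(seed = 6, n = 20, shift = 5)
  res <- mean_test(f$data, f$graph, B = 199, seed = 2)
  expect_equal(res$p_value, 1 / 200)
})

test_that("clique weights come from clique-level tests with strict meaningfulness", {
  g <- default_pathway_graph()
  sc <- ggm_scenario(g, n1 = 10, n2 = 10, seed = 21)
  d <- sample_scenario(sc)
  jt <- junction_tree(g)
  cw <- clique_tests(d, jt, B = 99, seed = 3, alpha = 0.05)
  expect_equal(cw$clique, names(jt$cliques))
  expect_true(all(cw$w > 0 & cw$w <= 1))
  expect_equal(cw$meaningful, cw$w < 0.05)
  # strictness at the boundary: alpha equal to an observed weight
  cw2 <- clique_tests(d, jt, B = 99, seed = 3, alpha = cw$w[1])
  expect_false(cw2$meaningful[1])
  # same permutation stream: weights reproducible
  cw3 <- clique_tests(d, jt, B = 99, seed = 3)
  expect_identical(cw$w, cw3$w)
})

test_that("single-gene pathways degrade to a variance-equality permutation test", {
  set.seed(8)
  x <- matrix(c(rnorm(10, sd = 1), rnorm(10, sd = 4)), 1,
              dimnames = list("g1", NULL))
  d <- expression_dataset(x, rep(c("A", "B"), each = 10))
  g1 <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(1, name = "g1")
  res <- concentration_test(d, g1, B = 199, seed = 4)
  expect_lt(res$p_value, 0.05)  # 4x sd difference must be caught
  jt <- sigpath:::prepare_jt(g1)
  cw <- clique_tests(d, jt, B = 199, seed = 4)
  expect_equal(nrow(cw), 1)
  expect_identical(cw$w[1], res$p_value)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(c(0.01, 0.5)), c(0.02, 1.0))
  expect_equal(bonferroni(0.2), 0.2)
  expect_equal(bonferroni(rep(0.6, 3)), rep(1, 3))
  p <- c(0.001, 0.02, 0.9)
  expect_true(all(bonferroni(p) >= p))
})
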