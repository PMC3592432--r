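# Step 1: permutation tests of equal concentration matrices
# ("homoschedasticity") and equal mean vectors between the two phenotype
# classes, on the whole pathway and on every clique. All statistics are
# -2 log likelihood-ratio (or monotone-equivalent quadratic-form) statistics
# computed from shrunken, graph-constrained covariance estimates and
# calibrated by permuting class labels; the shrinkage intensity is
# re-estimated inside every permutation.

# Accept a junction tree, a chordal/moral undirected graph, or a DAG, and
# return the junction tree the tests run on.
prepare_jt <- function(graph) {
  if (inherits(graph, "junction_tree")) return(graph)
  assert_named_graph(graph)
  if (igraph::is_directed(graph)) {
    if (!igraph::is_dag(graph))
      stop("directed graph has cycles; run break_cycles (needs expression data) first")
    graph <- moralize(graph)
  }
  if (!mcs(graph)$chordal) graph <- triangulate_graph(graph)
  junction_tree(graph)
}

# Permutation engine shared by all step-1 tests: one pass over a common
# permutation stream computes every statistic at once.
perm_engine <- function(data, graph, B = 1000, seed = NULL,
                        tol = 1e-8, max_iter = 5000) {
  data <- as_expression_dataset(data)
  jt <- prepare_jt(graph)
  genes <- sort(unique(unlist(jt$cliques)))
  miss <- setdiff(genes, rownames(data$x))
  if (length(miss))
    stop("graph genes missing from expression data: ",
         paste(miss, collapse = ", "))
  if (B < 19L) stop("B must be at least 19")
  x <- data$x[genes, , drop = FALSE]
  v <- apply(x, 1, stats::var)
  if (any(v <= 0))
    stop("zero-variance gene(s): ", paste(genes[v <= 0], collapse = ", "))
  n <- ncol(x)
  # class 1 = first n1 positions of each permuted order
  ord0 <- order(data$classes)
  # mean family permutes raw labels; the concentration family permutes the
  # columns of the Helmert-rotated residuals (iid under the Gaussian null of
  # equal concentrations, whatever the class means are)
  helmert <- function(m) {
    H <- stats::contr.helmert(m)
    H %*% diag(1 / sqrt(colSums(H^2)), m - 1L)
  }
  lv <- levels(data$classes)
  Z <- cbind(x[, data$classes == lv[1], drop = FALSE] %*% helmert(data$n1),
             x[, data$classes == lv[2], drop = FALSE] %*% helmert(data$n2))
  nz <- n - 2L
  ps <- with_seed(seed, list(
    X = cbind(ord0, replicate(B, ord0[sample.int(n)])),
    Z = cbind(seq_len(nz), replicate(B, sample.int(nz)))))
  gcliq <- indexed_cliques(jt, genes)                    # preorder, for IPS
  tcliq <- lapply(jt$cliques, function(cl) match(cl, genes))  # c1..cK order
  res <- perm_stats_cpp(x, ps$X, data$n1, Z, ps$Z, data$n1 - 1L,
                        gcliq, tcliq, tol, as.integer(max_iter))
  if (res$bad_splits > 0.01 * (B + 1))
    stop(sprintf(paste0(
      "IPS failed to converge in %d of %d permutations; ",
      "increase max_iter or loosen tol"), res$bad_splits, B + 1))
  st <- res$stats
  K <- length(jt$cliques)
  colnames(st) <- c("concentration", "mean_homo", "mean_hetero",
                    paste0("cc_", names(jt$cliques)),
                    paste0("cm_", names(jt$cliques)))
  obs <- st[1, ]
  pv <- vapply(seq_len(ncol(st)), function(j)
    (1 + sum(st[-1, j] >= st[1, j])) / (B + 1), 0)
  names(pv) <- colnames(st)
  list(jt = jt, observed = obs, p = pv, B = B,
       clique_ids = names(jt$cliques),
       bad_splits = res$bad_splits)
}

new_test_result <- function(statistic, p_value, n_perm, kind) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n_perm = n_perm, kind = kind),
            class = "sigpath_test")
}

#' @export
print.sigpath_test <- function(x, ...) {
  cat(sprintf("permutation test (%s): statistic = %.4g, p = %.4g (B = %d)\n",
              x$kind, x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Test equality of the two classes' concentration matrices
#'
#' Likelihood-ratio statistic
#' `2 * (l1(K1) + l2(K2) - l0(K0))` where each `K` is the IPS fit of the
#' class-specific (or pooled within-class) shrunken covariance to the graph,
#' calibrated by permuting class labels (add-one estimator, so `p >=
#' 1/(B+1)`). The shrinkage intensity is re-estimated within every
#' permutation.
#'
#' @param data an [expression_dataset()].
#' @param graph the pathway graph: a `junction_tree`, an undirected (moral)
#'   graph, or a DAG (moralized internally).
#' @param B number of permutations (>= 19).
#' @param seed integer seed for the permutation stream (NULL = current RNG).
#' @param tol,max_iter IPS controls.
#' @return a `sigpath_test` with `statistic`, `p_value`, `n_perm`, `kind`.
#' @export
concentration_test <- function(data, graph, B = 1000, seed = NULL,
                               tol = 1e-8, max_iter = 5000) {
  e <- perm_engine(data, graph, B, seed, tol, max_iter)
  new_test_result(e$observed["concentration"], e$p["concentration"], B,
                  "concentration")
}

#' Test equality of the two classes' mean vectors
#'
#' Homoschedastic variant: quadratic form `(n1 n2 / n) * delta' K delta` of
#' the mean difference in the metric of the common graph-constrained
#' concentration fitted to the pooled within-class shrunken covariance.
#' Heteroschedastic variant (Behrens-Fisher analog): `delta' (Sigma1/n1 +
#' Sigma2/n2)^{-1} delta` with class-specific graph-constrained fits. Both
#' are calibrated by label permutation, which makes any monotone-equivalent
#' form of the likelihood-ratio statistic valid.
#'
#' @inheritParams concentration_test
#' @param homoschedastic use the common-concentration variant (default) or
#'   the class-specific one.
#' @return a `sigpath_test`.
#' @export
mean_test <- function(data, graph, homoschedastic = TRUE, B = 1000,
                      seed = NULL, tol = 1e-8, max_iter = 5000) {
  e <- perm_engine(data, graph, B, seed, tol, max_iter)
  key <- if (homoschedastic) "mean_homo" else "mean_hetero"
  new_test_result(e$observed[key], e$p[key], B,
                  if (homoschedastic) "mean_homo" else "mean_hetero")
}

#' Clique-level tests and clique weights
#'
#' Runs the concentration (default) or mean test on every clique of the
#' junction tree. Cliques are complete, so no IPS is needed: the shrunken
#' covariances are used directly, and the statistic reduces to
#' `n log det Sp - n1 log det S1 - n2 log det S2` on the clique block (for a
#' single-gene clique this is the two-sample variance-ratio LRT). The
#' permutation p-value of each clique becomes its weight `w`; a weight is
#' meaningful when strictly below `alpha`.
#'
#' @inheritParams concentration_test
#' @param jt a `junction_tree` (or graph accepted by [concentration_test()]).
#' @param alpha meaningfulness cut-off for weights.
#' @param source which clique test provides the weights: the concentration
#'   test (as used for signal-path mining) or the mean test.
#' @return data.frame with `clique`, `w`, `meaningful` and attribute
#'   `junction_tree`.
#' @export
clique_tests <- function(data, jt, B = 1000, seed = NULL, alpha = 0.05,
                         source = c("concentration", "mean"),
                         tol = 1e-8, max_iter = 5000) {
  source <- match.arg(source)
  e <- perm_engine(data, jt, B, seed, tol, max_iter)
  pref <- if (source == "concentration") "cc_" else "cm_"
  w <- e$p[paste0(pref, e$clique_ids)]
  out <- data.frame(clique = e$clique_ids, w = unname(w),
                    meaningful = unname(w) < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "junction_tree") <- e$jt
  attr(out, "alpha") <- alpha
  out
}

#' Bonferroni adjustment
#'
#' `min(1, p * k)` across `k` tests.
#'
#' @param p vector of p-values in (0, 1].
#' @param k number of tests (defaults to `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, k = length(p)) {
  stats::p.adjust(p, method = "bonferroni", n = k)
}
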