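# Graph-constrained Gaussian estimation: James-Stein-type shrinkage of the
# sample covariance followed by iterative proportional scaling onto the set
# S+(G) of positive definite matrices whose inverse vanishes off the graph.

#' Shrinkage estimate of a covariance matrix
#'
#' Returns `(1 - lambda) * S + lambda * diag(S)` where `S` is the unbiased
#' sample covariance and `lambda` the analytically estimated optimal intensity
#' for shrinking correlations toward the identity (variances untouched),
#' clipped to `[0, 1]`. The estimate is positive definite whenever
#' `lambda > 0`, in particular when there are fewer samples than genes.
#'
#' @param x numeric matrix, variables in rows and samples (one class) in
#'   columns; at least 2 samples, no zero-variance row.
#' @param lambda optional fixed intensity overriding the analytic estimate.
#' @return object of class `shrunken_cov`: list with `sigma` (P x P matrix),
#'   `lambda`, `n`.
#' @export
shrink_covariance <- function(x, lambda = NULL) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 samples")
  if (anyNA(x)) stop("missing values in expression matrix")
  v <- apply(x, 1, stats::var)
  if (any(v <= 0))
    stop("zero-variance gene(s): ",
         paste(rownames(x)[v <= 0] %||% which(v <= 0), collapse = ", "))
  xc <- x - rowMeans(x)
  if (is.null(lambda)) {
    k <- shrink_cpp(xc, n - 1)
    sig <- k$sigma
    lambda <- k$lambda
  } else {
    stopifnot(lambda >= 0, lambda <= 1)
    S <- (xc %*% t(xc)) / (n - 1)
    sig <- (1 - lambda) * S
    diag(sig) <- diag(S)
  }
  dimnames(sig) <- list(rownames(x), rownames(x))
  structure(list(sigma = sig, lambda = lambda, n = n), class = "shrunken_cov")
}

#' @export
print.shrunken_cov <- function(x, ...) {
  cat(sprintf("shrunken covariance: %d x %d, lambda = %.4f, n = %d\n",
              nrow(x$sigma), ncol(x$sigma), x$lambda, x$n))
  invisible(x)
}

as_cov_matrix <- function(S) {
  if (inherits(S, "shrunken_cov")) S$sigma else as.matrix(S)
}

# cliques as integer index vectors into `genes`, in junction-tree preorder
indexed_cliques <- function(jt, genes, order = jt_preorder(jt)) {
  lapply(jt$cliques[order], function(cl) match(cl, genes))
}

#' Fit a graphical Gaussian model by iterative proportional scaling
#'
#' Projects a positive definite covariance onto the model whose concentration
#' matrix is zero off `graph`: IPS cycles over the maximal cliques of (a
#' triangulation of) the graph, at each step adjusting the concentration so
#' the fitted covariance matches `S` on the clique block, until the largest
#' absolute change of any fitted covariance entry over a full sweep falls
#' below `tol`. The constraint actually enforced is the triangulated graph's
#' zero pattern (fill-in edges are free parameters).
#'
#' @param S covariance: a `shrunken_cov` or a positive definite matrix with
#'   gene dimnames.
#' @param graph undirected `igraph` whose vertex names match the rows of `S`
#'   (it is triangulated internally if not chordal).
#' @param tol convergence tolerance on fitted covariance entries.
#' @param max_iter maximum number of full clique sweeps.
#' @param trace_loglik record the profile log-likelihood kernel
#'   `log det K - tr(K S)` after every sweep.
#' @return object of class `ggm_fit`: `sigma`, `concentration`, `graph` (the
#'   triangulated graph), `converged`, `iterations`, `tolerance_reached`,
#'   `cliques`, and optionally `loglik_trace`.
#' @export
ips_fit <- function(S, graph, tol = 1e-8, max_iter = 5000,
                    trace_loglik = FALSE) {
  Sm <- as_cov_matrix(S)
  assert_named_graph(graph)
  genes <- rownames(Sm)
  if (is.null(genes)) stop("covariance needs gene dimnames")
  if (!setequal(genes, igraph::V(graph)$name))
    stop("graph vertices and covariance dimnames differ")
  m <- mcs(graph)
  tg <- if (m$chordal) graph else triangulate_graph(graph)
  # connected graphs get the junction-tree preorder (a perfect sequence, so
  # IPS converges in very few sweeps); disconnected ones fall back to the
  # canonical clique order, which only costs extra sweeps
  cliques <- if (igraph::components(tg)$no == 1L) {
    jt <- junction_tree(tg)
    jt$cliques[jt_preorder(jt)]
  } else {
    cl <- canonical_clique_order(chordal_cliques(tg))
    stats::setNames(cl, paste0("c", seq_along(cl)))
  }
  cl <- lapply(cliques, function(x) match(x, genes))
  fit <- ips_cpp(Sm, cl, tol, as.integer(max_iter), trace_loglik)
  if (!fit$converged)
    warning("IPS did not converge in ", max_iter,
            " sweeps (last change ", format(fit$tolerance_reached), ")")
  dimnames(fit$sigma) <- dimnames(fit$concentration) <- dimnames(Sm)
  structure(list(sigma = fit$sigma, concentration = fit$concentration,
                 graph = tg, cliques = cliques,
                 converged = fit$converged, iterations = fit$iterations,
                 tolerance_reached = fit$tolerance_reached,
                 loglik_trace = if (trace_loglik) fit$loglik_trace),
            class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf(
    "graphical Gaussian fit: %d genes, %d cliques, %s after %d sweep(s)\n",
    nrow(x$sigma), length(x$cliques),
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Gaussian profile log-likelihood of a graph-constrained fit
#'
#' `(n/2) * (log det K - tr(K S))`, the multivariate normal log-likelihood
#' profiled over the mean, dropping the `-(nP/2) log(2*pi)` constant (the
#' same convention is used everywhere in the package, so only differences are
#' meaningful).
#'
#' @param fit a `ggm_fit`.
#' @param S the covariance the likelihood is evaluated against
#'   (`shrunken_cov` or matrix).
#' @param n number of samples behind `S`.
#' @return scalar log-likelihood (up to an additive constant).
#' @export
ggm_loglik <- function(fit, S, n) {
  Sm <- as_cov_matrix(S)
  K <- fit$concentration
  ev <- determinant(K, logarithm = TRUE)
  if (ev$sign <= 0) stop("concentration matrix is not positive definite")
  (n / 2) * (as.numeric(ev$modulus) - sum(K * Sm))
}

#' @export
logLik.ggm_fit <- function(object, S, n, ...) {
  ll <- ggm_loglik(object, S, n)
  attr(ll, "df") <- sum(object$concentration[upper.tri(object$concentration)] != 0) +
    nrow(object$sigma)
  class(ll) <- "logLik"
  ll
}
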