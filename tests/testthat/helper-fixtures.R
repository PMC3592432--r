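# Graph and data generators used across the suite. Everything is built in
# code under fixed seeds; no fixture files.

dgraph <- function(edges) {
  igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                              directed = TRUE)
}

ugraph <- function(edges) {
  igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                              directed = FALSE)
}

edge_set <- function(g) {
  el <- igraph::as_edgelist(g)
  if (!nrow(el)) return(character(0))
  if (igraph::is_directed(g)) sort(paste(el[, 1], el[, 2]))
  else sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

# random expression dataset for a set of genes (two balanced classes)
random_expr <- function(genes, n_per_class = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(length(genes) * 2 * n_per_class), length(genes),
              dimnames = list(genes, NULL))
  colnames(x) <- paste0("s", seq_len(ncol(x)))
  expression_dataset(x, rep(c("A", "B"), each = n_per_class))
}

# random DAG on p named nodes: orient random undirected edges by node order
random_dag <- function(p = 20, prob = 0.2, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(p))
  A <- matrix(runif(p * p) < prob, p, p)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  igraph::V(g)$name <- nodes
  g
}

# random connected decomposable graph on <= max_p nodes, built by
# triangulating a random connected undirected graph
random_decomposable <- function(max_p = 8, seed = 1) {
  set.seed(seed)
  repeat {
    p <- sample(3:max_p, 1)
    nodes <- letters[seq_len(p)]
    A <- matrix(runif(p * p) < 0.4, p, p)
    A <- A | t(A)
    diag(A) <- FALSE
    dimnames(A) <- list(nodes, nodes)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::components(g)$no == 1L) return(triangulate_graph(g))
  }
}

# well-conditioned random covariance with gene names
random_cov <- function(genes, n = 10 * length(genes), seed = 1) {
  set.seed(seed)
  p <- length(genes)
  X <- matrix(rnorm(p * n), p, n, dimnames = list(genes, NULL))
  cov(t(X))
}
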