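#' @useDynLib sigpath, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import igraph
#' @importFrom stats cor cov cutree hclust as.dist p.adjust rnorm runif
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means: use the current stream as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

sorted_vertex_names <- function(g) sort(igraph::V(g)$name)

assert_named_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("expected an igraph object")
  if (is.null(igraph::V(g)$name)) stop("graph vertices must be named (gene identifiers)")
  if (anyDuplicated(igraph::V(g)$name)) stop("duplicate gene identifiers in graph")
  invisible(g)
}

#' Remove self-loops from a pathway graph
#'
#' Edges of the form gene -> gene carry no information for a graphical model
#' and are dropped before cycle handling.
#'
#' @param g a directed `igraph` with named vertices.
#' @return the graph without loop edges; all other edges kept (parallel edges
#'   are also collapsed).
#' @export
remove_self_loops <- function(g) {
  assert_named_graph(g)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

# Find one directed cycle by DFS with lexicographic neighbor order, or NULL.
# Returns a character matrix of the cycle's edges (from, to).
find_directed_cycle <- function(g) {
  vs <- sorted_vertex_names(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "out"), function(x) sort(x$name))
  names(adj) <- igraph::V(g)$name
  color <- stats::setNames(rep(0L, length(vs)), vs)  # 0 white, 1 grey, 2 black
  parent <- stats::setNames(rep(NA_character_, length(vs)), vs)

  dfs <- function(start) {
    stack <- list(list(v = start, i = 1L))
    color[start] <<- 1L
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      nb <- adj[[fr$v]]
      if (fr$i <= length(nb)) {
        w <- nb[fr$i]
        stack[[length(stack)]]$i <- fr$i + 1L
        if (color[w] == 0L) {
          parent[w] <<- fr$v
          color[w] <<- 1L
          stack[[length(stack) + 1L]] <- list(v = w, i = 1L)
        } else if (color[w] == 1L) {
          # back edge fr$v -> w: walk parents from fr$v back to w
          cyc <- fr$v
          while (cyc[1] != w) cyc <- c(parent[cyc[1]], cyc)
          return(cbind(from = cyc, to = c(cyc[-1], w)))
        }
      } else {
        color[fr$v] <<- 2L
        stack[[length(stack)]] <- NULL
      }
    }
    NULL
  }
  for (v in vs) {
    if (color[v] == 0L) {
      res <- dfs(v)
      if (!is.null(res)) return(res)
    }
  }
  NULL
}

#' Break directed cycles using expression correlation
#'
#' Detected cycles are resolved one at a time by deleting, within the current
#' cycle, the edge whose endpoint expression profiles have the smallest
#' absolute Pearson correlation (samples of both classes pooled), until the
#' graph is acyclic. Cycle detection order is fixed by lexicographic vertex
#' order so runs are reproducible.
#'
#' @param g directed `igraph` without self-loops, every vertex measured in
#'   `expr`.
#' @param expr an [expression_dataset()] containing all graph genes.
#' @return an acyclic directed graph; only edges lying on some directed cycle
#'   are removed.
#' @export
break_cycles <- function(g, expr) {
  assert_named_graph(g)
  expr <- as_expression_dataset(expr)
  vn <- igraph::V(g)$name
  if (!all(vn %in% rownames(expr$x)))
    stop("graph genes missing from expression data: ",
         paste(setdiff(vn, rownames(expr$x)), collapse = ", "),
         " (use restrict_to_measured first)")
  if (any(igraph::which_loop(g))) stop("remove self-loops before breaking cycles")
  cm <- abs(stats::cor(t(expr$x[vn, , drop = FALSE])))
  repeat {
    cyc <- find_directed_cycle(g)
    if (is.null(cyc)) break
    cc <- cm[cbind(cyc[, "from"], cyc[, "to"])]
    if (all(is.na(cc)))
      stop("cannot break cycle: all edge correlations undefined (zero-variance genes?)")
    cc[is.na(cc)] <- Inf
    cand <- which(cc == min(cc))
    if (length(cand) > 1L) {
      key <- paste(cyc[cand, "from"], cyc[cand, "to"], sep = "\r")
      cand <- cand[order(key)][1L]
    }
    g <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, c(cyc[cand, "from"], cyc[cand, "to"])))
  }
  g
}

#' Moralize a DAG
#'
#' Parents sharing a child are joined ("married") and edge directions dropped,
#' yielding the undirected graph whose Markov structure the graphical Gaussian
#' models are constrained to.
#'
#' @param dag a directed acyclic `igraph`.
#' @return an undirected simple graph.
#' @export
moralize <- function(dag) {
  assert_named_graph(dag)
  if (!igraph::is_dag(dag)) stop("moralize requires an acyclic directed graph")
  und <- igraph::as_undirected(dag, mode = "collapse")
  extra <- character(0)
  for (v in igraph::V(dag)$name) {
    par <- sort(igraph::neighbors(dag, v, mode = "in")$name)
    if (length(par) >= 2L) {
      pr <- t(utils::combn(par, 2L))
      extra <- c(extra, as.vector(t(pr)))
    }
  }
  if (length(extra)) und <- igraph::add_edges(und, extra)
  igraph::simplify(und)
}

#' Triangulate an undirected graph (greedy minimum fill-in)
#'
#' Vertices are eliminated in greedy minimum-fill order with lexicographic
#' tie-breaking; fill edges completing each eliminated vertex's neighborhood
#' are inserted, so every cycle of length >= 4 in the output has a chord.
#' Minimum fill keeps maximal cliques small, which is what limits how many
#' samples the clique-wise covariance tests need.
#'
#' @param mg undirected `igraph` (typically a moral graph).
#' @return a chordal undirected graph with a logical edge attribute `fill`
#'   marking inserted edges.
#' @export
triangulate_graph <- function(mg) {
  assert_named_graph(mg)
  if (igraph::is_directed(mg)) stop("triangulation expects an undirected graph")
  vn <- sorted_vertex_names(mg)
  P <- length(vn)
  A <- matrix(FALSE, P, P, dimnames = list(vn, vn))
  el <- igraph::as_edgelist(mg)
  if (nrow(el)) {
    A[el] <- TRUE
    A[el[, 2:1, drop = FALSE]] <- TRUE
  }
  diag(A) <- FALSE
  fill <- matrix(character(0), ncol = 2)
  remaining <- rep(TRUE, P)
  work <- A
  for (step in seq_len(P)) {
    idx <- which(remaining)
    nfill <- vapply(idx, function(i) {
      nb <- which(work[i, ] & remaining)
      if (length(nb) < 2L) return(0L)
      sub <- work[nb, nb, drop = FALSE]
      as.integer((length(nb) * (length(nb) - 1L)) / 2L - sum(sub[upper.tri(sub)]))
    }, integer(1))
    v <- idx[which.min(nfill)]  # which.min takes the first = lexicographic
    nb <- which(work[v, ] & remaining)
    if (length(nb) >= 2L) {
      pairs <- utils::combn(nb, 2L)
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1, k]; j <- pairs[2, k]
        if (!work[i, j]) {
          work[i, j] <- work[j, i] <- TRUE
          A[i, j] <- A[j, i] <- TRUE
          fill <- rbind(fill, c(vn[i], vn[j]))
        }
      }
    }
    remaining[v] <- FALSE
  }
  out <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  if (igraph::ecount(out)) {
    elo <- igraph::as_edgelist(out)
    key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    igraph::E(out)$fill <- if (nrow(fill)) key(elo) %in% key(fill) else FALSE
  }
  out
}

#' Maximum cardinality search
#'
#' Orders vertices by repeatedly taking the vertex with the most already
#' numbered neighbors (ties to the lexicographically smallest name). The
#' ordering certifies chordality: the graph is chordal iff the numbered
#' neighbors of each vertex form a clique when it is numbered.
#'
#' @param g undirected `igraph`.
#' @return list with `order` (character vector of vertex names) and `chordal`
#'   (logical).
#' @export
mcs <- function(g) {
  assert_named_graph(g)
  vn <- sorted_vertex_names(g)
  P <- length(vn)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  A <- A[vn, vn, drop = FALSE]
  wt <- stats::setNames(rep(0L, P), vn)
  numbered <- stats::setNames(rep(FALSE, P), vn)
  ord <- character(P)
  chordal <- TRUE
  for (i in seq_len(P)) {
    cand <- vn[!numbered]
    v <- cand[which.max(wt[cand])]  # which.max first = lexicographic tie-break
    ord[i] <- v
    prev <- vn[numbered & A[v, ]]
    if (length(prev) >= 2L) {
      sub <- A[prev, prev, drop = FALSE]
      if (!all(sub[upper.tri(sub)])) chordal <- FALSE
    }
    numbered[v] <- TRUE
    nb <- vn[A[v, ] & !numbered]
    wt[nb] <- wt[nb] + 1L
  }
  list(order = ord, chordal = chordal)
}

#' Maximal cliques of a chordal graph
#'
#' @param cg chordal undirected `igraph`.
#' @return list of character vectors (sorted gene names), in a canonical
#'   deterministic order.
#' @export
chordal_cliques <- function(cg) {
  assert_named_graph(cg)
  cl <- lapply(igraph::max_cliques(cg), function(v) sort(v$name))
  cl[order(vapply(cl, paste, "", collapse = "\r"))]
}

canonical_clique_order <- function(cliques) {
  cliques[order(vapply(cliques, paste, "", collapse = "\r"))]
}

# ---------------------------------------------------------------------------
# Junction tree
# ---------------------------------------------------------------------------

new_junction_tree <- function(cliques, edges, root, validate = TRUE) {
  if (is.null(names(cliques)))
    names(cliques) <- paste0("c", seq_along(cliques))
  cliques <- lapply(cliques, function(x) sort(as.character(x)))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) names(edges)[1:2] <- c("from", "to")
  seps <- if (nrow(edges))
    lapply(seq_len(nrow(edges)),
           function(i) intersect(cliques[[edges$from[i]]], cliques[[edges$to[i]]]))
  else list()
  jt <- structure(
    list(cliques = cliques,
         edges = edges[, c("from", "to"), drop = FALSE],
         separators = seps,
         root = root),
    class = "junction_tree")
  if (validate) validate_junction_tree(jt)
  jt
}

validate_junction_tree <- function(jt) {
  K <- length(jt$cliques)
  ids <- names(jt$cliques)
  if (!jt$root %in% ids) stop("root is not a clique id")
  if (nrow(jt$edges) != K - 1L) stop("junction tree must have |cliques| - 1 edges")
  if (K > 1L) {
    tg <- igraph::graph_from_data_frame(jt$edges, directed = FALSE,
                                        vertices = ids)
    if (igraph::components(tg)$no != 1L) stop("junction tree edges are not connected")
  }
  if (!check_rip(jt)) stop("running intersection property violated")
  invisible(jt)
}

jt_igraph <- function(jt) {
  igraph::graph_from_data_frame(
    if (nrow(jt$edges)) jt$edges else data.frame(from = character(0), to = character(0)),
    directed = FALSE, vertices = names(jt$cliques))
}

jt_path_between <- function(jt, a, b) {
  if (length(jt$cliques) == 1L) return(names(jt$cliques))
  g <- jt_igraph(jt)
  p <- igraph::shortest_paths(g, from = a, to = b, output = "vpath")$vpath[[1]]
  p$name
}

#' Check the running intersection property
#'
#' For every pair of cliques, every clique on the tree path between them must
#' contain their intersection.
#'
#' @param jt a junction tree.
#' @return logical.
#' @export
check_rip <- function(jt) {
  ids <- names(jt$cliques)
  if (length(ids) <= 2L) return(TRUE)
  g <- jt_igraph(jt)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      inter <- intersect(jt$cliques[[i]], jt$cliques[[j]])
      if (!length(inter)) next
      p <- igraph::shortest_paths(g, from = ids[i], to = ids[j],
                                  output = "vpath")$vpath[[1]]$name
      for (c_on in p)
        if (!all(inter %in% jt$cliques[[c_on]])) return(FALSE)
    }
  }
  TRUE
}

#' Build a rooted junction tree from a chordal graph
#'
#' A maximum-weight spanning tree on the clique-intersection graph (weight =
#' separator size, Kruskal order with lexicographic tie-break) guarantees the
#' running intersection property for chordal graphs. The root is the clique
#' whose vertices come earliest in the maximum cardinality search ordering.
#'
#' @param cg chordal undirected `igraph`; must be connected (split a
#'   disconnected pathway into components first, see
#'   [restrict_to_measured()] and [sigpath()] which do this automatically).
#' @param cliques optional precomputed maximal cliques.
#' @return object of class `junction_tree`: named clique gene sets, tree
#'   edges with separators, and the root clique id.
#' @export
junction_tree <- function(cg, cliques = NULL) {
  assert_named_graph(cg)
  if (igraph::is_directed(cg)) stop("junction_tree expects an undirected graph")
  if (igraph::components(cg)$no != 1L)
    stop("graph is disconnected; build one junction tree per component")
  m <- mcs(cg)
  if (!m$chordal) stop("graph is not chordal; triangulate first")
  cliques <- canonical_clique_order(cliques %||% chordal_cliques(cg))
  K <- length(cliques)
  ids <- paste0("c", seq_len(K))
  names(cliques) <- ids

  edges <- data.frame(from = character(0), to = character(0))
  if (K > 1L) {
    cand <- list()
    for (i in seq_len(K - 1L)) {
      for (j in seq(i + 1L, K)) {
        w <- length(intersect(cliques[[i]], cliques[[j]]))
        if (w > 0L) cand[[length(cand) + 1L]] <- c(i, j, w)
      }
    }
    if (!length(cand)) stop("clique intersection graph is disconnected")
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    parent <- seq_len(K)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    picked <- matrix(integer(0), ncol = 2)
    for (r in seq_len(nrow(cand))) {
      a <- find(cand[r, 1]); b <- find(cand[r, 2])
      if (a != b) {
        parent[a] <- b
        picked <- rbind(picked, cand[r, 1:2])
        if (nrow(picked) == K - 1L) break
      }
    }
    if (nrow(picked) != K - 1L)
      stop("clique intersection graph is disconnected")
    edges <- data.frame(from = ids[picked[, 1]], to = ids[picked[, 2]],
                        stringsAsFactors = FALSE)
  }

  # root: clique whose members' MCS positions are lexicographically smallest
  pos <- stats::setNames(seq_along(m$order), m$order)
  keys <- vapply(cliques, function(cl)
    paste(sprintf("%06d", sort(pos[cl])), collapse = ""), "")
  root <- ids[order(keys)][1L]
  new_junction_tree(cliques, edges, root, validate = FALSE)
}

#' @export
print.junction_tree <- function(x, ...) {
  K <- length(x$cliques)
  cat("Junction tree:", K, "clique(s), root", x$root, "\n")
  lv <- jt_leaves(x)
  cat("Leaves:", paste(lv, collapse = ", "), "\n")
  sizes <- lengths(x$cliques)
  cat("Clique sizes:", paste(sizes, collapse = " "),
      sprintf(" (largest %d)\n", max(sizes)))
  invisible(x)
}

#' Leaf cliques of a junction tree
#' @param jt a junction tree.
#' @return character vector of leaf clique ids (degree one, excluding the
#'   root unless the tree is a single clique).
#' @export
jt_leaves <- function(jt) {
  ids <- names(jt$cliques)
  if (length(ids) == 1L) return(ids)
  deg <- table(factor(c(jt$edges$from, jt$edges$to), levels = ids))
  setdiff(ids[deg == 1L], jt$root)
}

# Cliques in preorder from the root (a perfect sequence for a chordal graph's
# clique tree); IPS converges in very few sweeps in this order.
jt_preorder <- function(jt) {
  ids <- names(jt$cliques)
  if (length(ids) == 1L) return(ids)
  g <- jt_igraph(jt)
  igraph::dfs(g, root = jt$root)$order$name
}
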