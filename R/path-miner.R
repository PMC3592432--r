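# Step 2: mining signal sub-paths along root-to-leaf junction-tree paths.
# Clique weights (clique-level test p-values) lose their probability
# interpretation here and act as scores: a running relevance accumulates
# along each candidate chain of cliques, length-standardized so chains of
# different lengths compare fairly, and near-duplicate gene sets among the
# per-path winners are collapsed by clustering on a set dissimilarity.

#' Scoring policy for sub-path relevance and dissimilarity
#'
#' All step-2 scoring formulas live in this one object so an alternative
#' convention replaces a single code site:
#' * `increment(w)`: per-clique contribution to the running score,
#'   default `1 - 2 w` (0.5 is neutral, small weights push up);
#' * `standardize(r, m)`: length standardization of the maximal running
#'   score, default `r / m` with `m` the (first) position of the maximum;
#' * `dissimilarity(A, B)`: gene-set dissimilarity in `[0, 1]`, default
#'   `min(|A \ B| / |A|, |B \ A| / |B|)` (0 for nested sets, 1 for disjoint);
#' * `alpha`: weight meaningfulness cut-off (default 0.05);
#' * `t`: collapse threshold on the dissimilarity (default 0.2).
#'
#' @param increment,standardize,dissimilarity replacement functions.
#' @param alpha,t replacement thresholds.
#' @return object of class `scoring_policy`.
#' @export
scoring_policy <- function(increment = function(w) 1 - 2 * w,
                           standardize = function(r, m) r / m,
                           dissimilarity = function(A, B)
                             min(length(setdiff(A, B)) / length(A),
                                 length(setdiff(B, A)) / length(B)),
                           alpha = 0.05, t = 0.2) {
  stopifnot(alpha > 0, alpha < 1, t >= 0, t <= 1)
  structure(list(increment = increment, standardize = standardize,
                 dissimilarity = dissimilarity, alpha = alpha, t = t),
            class = "scoring_policy")
}

#' Root-to-leaf paths of a junction tree
#'
#' @param jt a `junction_tree`.
#' @return list of character vectors of clique ids, one per leaf, each
#'   starting at the root; a single-clique tree yields one degenerate path.
#' @export
tree_paths <- function(jt) {
  if (length(jt$cliques) == 1L) return(list(names(jt$cliques)))
  lapply(jt_leaves(jt), function(lf) jt_path_between(jt, jt$root, lf))
}

new_subpath <- function(path_id, clique_ids, start, w, jt = NULL) {
  genes <- if (!is.null(jt)) sort(unique(unlist(jt$cliques[clique_ids])))
  structure(list(path = path_id, cliques = clique_ids, start = as.integer(start),
                 l = length(clique_ids), w = unname(w), genes = genes),
            class = "subpath")
}

#' @export
print.subpath <- function(x, ...) {
  cat(sprintf("sub-path [%s] (l = %d%s)\n",
              paste(x$cliques, collapse = " - "), x$l,
              if (!is.null(x$r_star)) sprintf(", r = %.3f, m = %d, r* = %.3f",
                                              x$r, x$m, x$r_star) else ""))
  invisible(x)
}

#' Candidate sub-paths of one junction-tree path
#'
#' A candidate is a contiguous segment of the path that starts and ends at a
#' meaningful clique (weight strictly below `alpha`) and contains at most one
#' non-meaningful clique. Both granularities are returned: every maximal
#' all-meaningful run, and, whenever exactly one non-meaningful clique
#' separates two runs, the bridged segment as well.
#'
#' @param path character vector of clique ids (root to leaf).
#' @param weights named numeric vector of clique weights covering `path`.
#' @param alpha meaningfulness cut-off.
#' @param jt optional junction tree supplying clique gene sets.
#' @param path_id label recorded on each candidate.
#' @return list of `subpath` objects (empty when no clique is meaningful).
#' @export
extract_subpaths <- function(path, weights, alpha = 0.05, jt = NULL,
                             path_id = paste(path[1], path[length(path)],
                                             sep = ">")) {
  w <- weights[path]
  if (anyNA(w)) stop("weights missing for cliques: ",
                     paste(path[is.na(w)], collapse = ", "))
  flag <- w < alpha
  if (!any(flag)) return(list())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  segs <- lapply(runs, function(k) c(starts[k], ends[k]))
  for (i in seq_along(runs)) {
    if (i == length(runs)) break
    k1 <- runs[i]; k2 <- runs[i + 1L]
    if (k2 - k1 == 2L && r$lengths[k1 + 1L] == 1L)  # single-clique gap
      segs[[length(segs) + 1L]] <- c(starts[k1], ends[k2])
  }
  segs <- unique(segs)
  segs <- segs[order(vapply(segs, `[`, 0, 1), vapply(segs, `[`, 0, 2))]
  lapply(segs, function(s) {
    idx <- seq(s[1], s[2])
    new_subpath(path_id, path[idx], s[1], w[idx], jt)
  })
}

#' Relevance of a sub-path
#'
#' Respecting clique order, accumulates the running score `o_i = o_{i-1} +
#' increment(w_i)` (with `o_0 = 0`); the relevance `r` is the maximum of the
#' running scores and `m` the first position attaining it.
#'
#' @param w weights of the sub-path's cliques, in order.
#' @param policy a [scoring_policy()].
#' @return list with `r`, `m`, and the running scores `o`.
#' @export
relevance <- function(w, policy = scoring_policy()) {
  if (inherits(w, "subpath")) w <- w$w
  if (!length(w)) stop("empty sub-path")
  o <- cumsum(policy$increment(w))
  m <- which.max(o)  # first maximum
  list(r = o[[m]], m = as.integer(m), o = unname(o))
}

#' Length-standardized relevance
#'
#' Makes sub-paths of different lengths comparable; with the default policy
#' `r_star = r / m`, so a maximum reached early is worth more than the same
#' score reached late.
#'
#' @param r relevance.
#' @param m position of the maximum running score.
#' @param policy a [scoring_policy()].
#' @return scalar standardized relevance.
#' @export
standardized_relevance <- function(r, m, policy = scoring_policy()) {
  stopifnot(m >= 1)
  policy$standardize(r, m)
}

score_subpath <- function(sp, policy = scoring_policy()) {
  rv <- relevance(sp$w, policy)
  sp$r <- rv$r
  sp$m <- rv$m
  sp$o <- rv$o
  sp$r_star <- standardized_relevance(rv$r, rv$m, policy)
  sp
}

#' Best sub-path of a path
#'
#' The candidate with maximal standardized relevance; ties go to the longer
#' sub-path, then to the earlier start position.
#'
#' @param subpaths list of `subpath` candidates (may be unscored).
#' @param policy a [scoring_policy()].
#' @return the winning scored `subpath`, or `NULL` for an empty candidate
#'   list (a path with no meaningful clique has no relevant sub-path).
#' @export
best_subpath <- function(subpaths, policy = scoring_policy()) {
  if (!length(subpaths)) return(NULL)
  scored <- lapply(subpaths, function(sp)
    if (is.null(sp$r_star)) score_subpath(sp, policy) else sp)
  key <- order(-vapply(scored, `[[`, 0, "r_star"),
               -vapply(scored, `[[`, 0L, "l"),
               vapply(scored, `[[`, 0L, "start"))
  scored[[key[1]]]
}

#' Dissimilarity between two sub-paths' gene sets
#'
#' With the default policy `d(A, B) = min(|A \ B| / |A|, |B \ A| / |B|)`:
#' zero when one gene set contains the other (nested sub-paths collapse), one
#' when they are disjoint; symmetric.
#'
#' @param A,B `subpath` objects or character vectors of genes (non-empty).
#' @param policy a [scoring_policy()].
#' @return dissimilarity in `[0, 1]`.
#' @export
subpath_dissimilarity <- function(A, B, policy = scoring_policy()) {
  a <- if (inherits(A, "subpath")) A$genes else as.character(A)
  b <- if (inherits(B, "subpath")) B$genes else as.character(B)
  if (!length(a) || !length(b)) stop("empty gene set")
  policy$dissimilarity(unique(a), unique(b))
}

#' Collapse overlapping sub-paths
#'
#' Hierarchical clustering on the pairwise gene-set dissimilarity, cut at
#' height `t`; each cluster is represented by its member with the highest
#' standardized relevance (ties: higher relevance, then first). With the
#' default single linkage any two sub-paths with `d <= t` end up in the same
#' cluster, so representatives are pairwise more dissimilar than `t`.
#'
#' @param subpaths list of scored `subpath` objects (the per-path winners).
#' @param t collapse threshold (defaults to the policy's).
#' @param policy a [scoring_policy()].
#' @param method linkage passed to [stats::hclust()].
#' @return object of class `subpath_report`: list with `subpaths` (all
#'   inputs, each annotated with `cluster` and `representative`),
#'   `representatives` (list of winning sub-paths), `t`, `alpha`.
#' @export
prune_subpaths <- function(subpaths, t = policy$t, policy = scoring_policy(),
                           method = "single") {
  subpaths <- lapply(subpaths, function(sp)
    if (is.null(sp$r_star)) score_subpath(sp, policy) else sp)
  n <- length(subpaths)
  if (n == 0L)
    return(structure(list(subpaths = list(), representatives = list(),
                          t = t, alpha = policy$alpha),
                     class = "subpath_report"))
  cl <- rep(1L, n)
  if (n > 1L) {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L))
      for (j in seq(i + 1L, n))
        D[i, j] <- D[j, i] <- subpath_dissimilarity(subpaths[[i]],
                                                    subpaths[[j]], policy)
    hc <- stats::hclust(stats::as.dist(D), method = method)
    cl <- stats::cutree(hc, h = t)
  }
  reps <- integer(0)
  for (k in sort(unique(cl))) {
    idx <- which(cl == k)
    key <- order(-vapply(subpaths[idx], `[[`, 0, "r_star"),
                 -vapply(subpaths[idx], `[[`, 0, "r"),
                 idx)
    reps <- c(reps, idx[key[1]])
  }
  for (i in seq_len(n)) {
    subpaths[[i]]$cluster <- unname(cl[i])
    subpaths[[i]]$representative <- i %in% reps
  }
  structure(list(subpaths = subpaths, representatives = subpaths[reps],
                 t = t, alpha = policy$alpha),
            class = "subpath_report")
}

#' @export
print.subpath_report <- function(x, ...) {
  cat(sprintf("signal sub-paths: %d candidate(s), %d after collapse (t = %g)\n",
              length(x$subpaths), length(x$representatives), x$t))
  for (sp in x$representatives) print(sp)
  invisible(x)
}

#' Mine signal sub-paths of a junction tree
#'
#' Full step-2 procedure: enumerate root-to-leaf paths, extract candidate
#' sub-paths from the clique weights, select the best sub-path of each path
#' by standardized relevance, and collapse near-duplicate winners.
#'
#' @param jt a `junction_tree`.
#' @param weights named clique weights (e.g. the `w` column of
#'   [clique_tests()], named by clique), or a `clique_tests` data.frame.
#' @param policy a [scoring_policy()]; its `alpha` and `t` are used.
#' @return a `subpath_report`; additionally carries `paths` and `best` (the
#'   per-path winners, `NULL`-free).
#' @export
mine_subpaths <- function(jt, weights, policy = scoring_policy()) {
  if (is.data.frame(weights))
    weights <- stats::setNames(weights$w, weights$clique)
  paths <- tree_paths(jt)
  best <- list()
  for (i in seq_along(paths)) {
    cand <- extract_subpaths(paths[[i]], weights, policy$alpha, jt,
                             path_id = paste0("p", i))
    b <- best_subpath(cand, policy)
    if (!is.null(b)) best[[length(best) + 1L]] <- b
  }
  rep <- prune_subpaths(best, policy$t, policy)
  rep$paths <- paths
  rep$best <- best
  rep
}

# Length of the top relevant sub-path (max r_star among per-path winners);
# 0 when no path has a meaningful clique.
top_subpath_length <- function(report) {
  if (!length(report$best)) return(0L)
  rs <- vapply(report$best, `[[`, 0, "r_star")
  report$best[[which.max(rs)]]$l
}

#' Illustrative junction tree and clique weights
#'
#' A 12-clique junction tree (root `c1`, leaves `c8`, `c10`, `c12`) with a
#' weight pattern under which the root-to-`c8` path decomposes into four
#' candidate sub-paths. Useful for demonstrating the miner without running
#' any test.
#'
#' @return list with `jt` (a `junction_tree`) and `weights` (named numeric).
#' @export
example_junction_tree <- function() {
  # chain c1..c8 with branches c5-c9-c10 and c3-c11-c12; each clique has a
  # private gene plus one shared gene per tree edge
  edges <- data.frame(
    from = c("c1", "c2", "c3", "c4", "c5", "c6", "c7", "c5", "c9", "c3", "c11"),
    to   = c("c2", "c3", "c4", "c5", "c6", "c7", "c8", "c9", "c10", "c11", "c12"),
    stringsAsFactors = FALSE)
  ids <- paste0("c", 1:12)
  cliques <- stats::setNames(lapply(ids, function(id) paste0("u_", id)), ids)
  for (i in seq_len(nrow(edges))) {
    s <- paste0("s_", edges$from[i], "_", edges$to[i])
    cliques[[edges$from[i]]] <- c(cliques[[edges$from[i]]], s)
    cliques[[edges$to[i]]] <- c(cliques[[edges$to[i]]], s)
  }
  jt <- new_junction_tree(cliques, edges, root = "c1")
  weights <- stats::setNames(rep(0.60, 12), ids)
  weights[c("c1", "c4", "c6", "c7")] <- c(0.02, 0.01, 0.03, 0.04)
  weights["c9"] <- 0.35
  list(jt = jt, weights = weights)
}
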