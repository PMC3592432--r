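# Synthetic two-class data from graphical Gaussian models: null scenarios
# (both classes from the same model) for type-I-error calibration, and
# alternative scenarios with mean shifts and concentration perturbations
# confined to chosen cliques for power / signal-path recovery checks.

#' Default simulation pathway graph
#'
#' A 12-gene decomposable graph made of five cliques
#' `{g01..g04}, {g04..g06}, {g06..g08}, {g08..g10}, {g10..g12}` chained by
#' single-gene separators, so its junction tree is a single root-to-leaf path
#' of five cliques (largest clique size 4). Small enough for desk-scale
#' simulation, long enough to host multi-clique sub-paths.
#'
#' @return undirected `igraph`.
#' @export
default_pathway_graph <- function() {
  genes <- sprintf("g%02d", 1:12)
  cliques <- list(genes[1:4], genes[4:6], genes[6:8], genes[8:10], genes[10:12])
  el <- do.call(rbind, lapply(cliques, function(cl) t(utils::combn(cl, 2))))
  g <- igraph::graph_from_edgelist(unique(el), directed = FALSE)
  igraph::simplify(g)
}

#' Random graph-constrained concentration matrix
#'
#' Assigns each graph edge a partial-correlation-like entry with magnitude
#' uniform in `pc_range` and random sign, then makes the matrix strictly
#' diagonally dominant with margin `conditioning`, which guarantees positive
#' definiteness with smallest eigenvalue at least `conditioning` (Gershgorin)
#' and exact zeros off the graph.
#'
#' @param graph undirected `igraph`.
#' @param seed optional integer seed (NULL = current RNG stream).
#' @param conditioning lower bound on the smallest eigenvalue.
#' @param pc_range magnitude range of off-diagonal entries.
#' @return symmetric positive definite matrix with gene dimnames.
#' @export
random_ggm <- function(graph, seed = NULL, conditioning = 0.5,
                       pc_range = c(0.1, 0.4)) {
  assert_named_graph(graph)
  stopifnot(conditioning > 0)
  vn <- sorted_vertex_names(graph)
  P <- length(vn)
  K <- matrix(0, P, P, dimnames = list(vn, vn))
  el <- igraph::as_edgelist(graph)
  with_seed(seed, {
    if (nrow(el)) {
      vals <- stats::runif(nrow(el), pc_range[1], pc_range[2]) *
        sample(c(-1, 1), nrow(el), replace = TRUE)
      K[el] <- vals
      K[el[, 2:1, drop = FALSE]] <- vals
    }
  })
  diag(K) <- rowSums(abs(K)) + conditioning
  K
}

#' Two-class graphical Gaussian scenario
#'
#' Bundles the graph, the two mean vectors and the two graph-constrained
#' concentration matrices defining the data-generating models, plus sample
#' sizes. Defaults give a null scenario (identical models).
#'
#' @param graph undirected `igraph`.
#' @param K1,K2 concentration matrices (default: one [random_ggm()] draw
#'   shared by both classes).
#' @param mu1,mu2 mean vectors (scalars recycled).
#' @param n1,n2 per-class sample sizes.
#' @param seed optional seed used for defaulted `K1` and recorded for
#'   [sample_scenario()].
#' @return object of class `ggm_scenario`.
#' @export
ggm_scenario <- function(graph, K1 = NULL, K2 = NULL, mu1 = 0, mu2 = 0,
                         n1 = 20, n2 = 20, seed = NULL) {
  assert_named_graph(graph)
  vn <- sorted_vertex_names(graph)
  P <- length(vn)
  if (is.null(K1)) K1 <- random_ggm(graph, seed = seed)
  if (is.null(K2)) K2 <- K1
  check_K <- function(K, nm) {
    if (!isTRUE(all.equal(K, t(K)))) stop(nm, " is not symmetric")
    A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)[vn, vn] > 0
    off <- K[vn, vn]
    off[A | diag(P) > 0] <- 0
    if (any(off != 0)) stop(nm, " has non-zero entries off the graph")
    if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop(nm, " is not positive definite")
  }
  check_K(K1, "K1"); check_K(K2, "K2")
  expand <- function(mu) {
    if (length(mu) == 1L) mu <- rep(mu, P)
    stats::setNames(as.numeric(mu), vn)
  }
  structure(list(graph = graph, genes = vn,
                 K1 = K1[vn, vn], K2 = K2[vn, vn],
                 mu1 = expand(mu1), mu2 = expand(mu2),
                 n1 = as.integer(n1), n2 = as.integer(n2), seed = seed),
            class = "ggm_scenario")
}

#' Draw a two-class dataset from a scenario
#'
#' Samples `n1` observations from `N(mu1, K1^{-1})` and `n2` from
#' `N(mu2, K2^{-1})` via the Cholesky factor of each concentration matrix.
#'
#' @param sc a [ggm_scenario()].
#' @param seed optional seed (defaults to the scenario's).
#' @return an [expression_dataset()] with classes `A` and `B`.
#' @export
sample_scenario <- function(sc, seed = sc$seed) {
  stopifnot(inherits(sc, "ggm_scenario"))
  P <- length(sc$genes)
  draw <- function(K, mu, n) {
    U <- chol(K)                       # K = U'U, Sigma = U^{-1} U^{-T}
    Z <- matrix(stats::rnorm(P * n), P, n)
    backsolve(U, Z) + mu
  }
  x <- with_seed(seed, {
    cbind(draw(sc$K1, sc$mu1, sc$n1), draw(sc$K2, sc$mu2, sc$n2))
  })
  rownames(x) <- sc$genes
  colnames(x) <- c(sprintf("A%03d", seq_len(sc$n1)),
                   sprintf("B%03d", seq_len(sc$n2)))
  expression_dataset(x, rep(c("A", "B"), c(sc$n1, sc$n2)))
}

derive_run_seeds <- function(seed, runs) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, runs))
}

#' Null calibration study
#'
#' For each run, both classes are drawn from the same graphical Gaussian
#' model (a fresh [random_ggm()] per run) and the whole-pathway concentration
#' and mean tests plus all clique tests are performed; step 2 is then run on
#' the clique weights. Reports per-test rejection percentages at level
#' `alpha` and the distribution of the top relevant sub-path length. The
#' mean-test variant follows the pipeline rule: heteroschedastic when the
#' run's concentration test rejects at `alpha`, homoschedastic otherwise.
#' A master seed derives one sub-seed per run, so any run is independently
#' reproducible.
#'
#' @param runs number of simulation runs.
#' @param graph undirected pathway graph (default [default_pathway_graph()]).
#' @param n1,n2 per-class sample sizes.
#' @param alpha nominal level.
#' @param B permutations per test.
#' @param seed master seed.
#' @param tol,max_iter IPS controls.
#' @return object of class `null_study`: per-run data.frame `runs` and a
#'   `summary` list with rejection percentages (`concentration`, `mean`,
#'   `mean_homo`, `mean_hetero`), `pct_top_longer_than_1`, and the top-length
#'   table.
#' @export
null_study <- function(runs = 1000, graph = default_pathway_graph(),
                       n1 = 20, n2 = 20, alpha = 0.05, B = 1000, seed = 1,
                       tol = 1e-8, max_iter = 5000) {
  jt <- prepare_jt(graph)
  policy <- scoring_policy(alpha = alpha)
  seeds <- derive_run_seeds(seed, runs)
  rows <- vector("list", runs)
  for (i in seq_len(runs)) {
    rows[[i]] <- with_seed(seeds[i], {
      sc <- ggm_scenario(graph, n1 = n1, n2 = n2)
      data <- sample_scenario(sc, seed = NULL)
      e <- perm_engine(data, jt, B = B, seed = NULL,
                       tol = tol, max_iter = max_iter)
      w <- stats::setNames(e$p[paste0("cc_", e$clique_ids)], e$clique_ids)
      rep <- mine_subpaths(jt, w, policy)
      data.frame(run = i,
                 p_concentration = unname(e$p["concentration"]),
                 p_mean_homo = unname(e$p["mean_homo"]),
                 p_mean_hetero = unname(e$p["mean_hetero"]),
                 p_clique1 = unname(w[1]),
                 clique_reject_frac = mean(w < alpha),
                 n_meaningful = sum(w < alpha),
                 top_length = top_subpath_length(rep))
    })
  }
  df <- do.call(rbind, rows)
  df$p_mean <- ifelse(df$p_concentration < alpha,
                      df$p_mean_hetero, df$p_mean_homo)
  pct <- function(x) 100 * mean(x)
  summ <- list(
    runs = runs, alpha = alpha, B = B, n1 = n1, n2 = n2,
    reject_pct = c(concentration = pct(df$p_concentration < alpha),
                   mean = pct(df$p_mean < alpha),
                   mean_homo = pct(df$p_mean_homo < alpha),
                   mean_hetero = pct(df$p_mean_hetero < alpha)),
    pct_top_longer_than_1 = pct(df$top_length > 1),
    top_length_table = table(df$top_length))
  structure(list(runs = df, summary = summ), class = "null_study")
}

#' @export
print.null_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("null study: %d runs, n = %d/%d, B = %d, alpha = %g\n",
              s$runs, s$n1, s$n2, s$B, s$alpha))
  cat("rejection % at alpha:\n")
  print(round(s$reject_pct, 2))
  cat(sprintf("top relevant sub-path longer than 1 clique: %.2f%% of runs\n",
              s$pct_top_longer_than_1))
  invisible(x)
}

# cliques (by id) of a junction tree that a perturbation targets
target_gene_set <- function(jt, target_cliques) {
  miss <- setdiff(target_cliques, names(jt$cliques))
  if (length(miss)) stop("unknown target clique(s): ",
                         paste(miss, collapse = ", "))
  sort(unique(unlist(jt$cliques[target_cliques])))
}

#' Perturbed two-class scenario localized to cliques
#'
#' Builds an alternative scenario from a base [random_ggm()] draw: within the
#' target cliques the class-2 concentration entries have their signs flipped
#' (preserving positive definiteness by diagonal dominance) and the class-2
#' means of the target cliques' genes are shifted by `effect_sd` marginal
#' standard deviations.
#'
#' @param graph undirected pathway graph.
#' @param jt its junction tree (defaults to building one).
#' @param target_cliques clique ids carrying the signal.
#' @param effect_sd mean shift in units of each gene's marginal sd.
#' @param flip_concentration flip signs of within-target partial
#'   correlations.
#' @param n1,n2 sample sizes.
#' @param seed optional seed for the base model draw.
#' @return a [ggm_scenario()].
#' @export
perturbed_scenario <- function(graph, jt = prepare_jt(graph),
                               target_cliques, effect_sd = 5,
                               flip_concentration = TRUE,
                               n1 = 50, n2 = 50, seed = NULL) {
  K1 <- random_ggm(graph, seed = seed)
  genes <- target_gene_set(jt, target_cliques)
  K2 <- K1
  if (flip_concentration) {
    idx <- rownames(K1) %in% genes
    blk <- K2[idx, idx]
    off <- blk
    diag(off) <- 0
    K2[idx, idx] <- blk - 2 * off     # flip off-diagonal signs in the block
  }
  sds <- sqrt(diag(solve(K1)))
  mu2 <- stats::setNames(rep(0, nrow(K1)), rownames(K1))
  mu2[genes] <- effect_sd * sds[genes]
  ggm_scenario(graph, K1 = K1, K2 = K2, mu1 = 0, mu2 = mu2,
               n1 = n1, n2 = n2)
}

#' Signal-path recovery study
#'
#' For each run, data are drawn from a [perturbed_scenario()] and the full
#' clique-test + miner pipeline is applied; a run counts as a recovery when
#' the top relevant sub-path contains at least one target clique. The Jaccard
#' index between the top sub-path's cliques and the target cliques is also
#' reported.
#'
#' @param runs number of runs.
#' @param graph undirected pathway graph.
#' @param target_cliques clique ids carrying the signal (defaults to the two
#'   middle cliques of the junction tree).
#' @param effect_sd mean shift in marginal sd units (0 = null).
#' @param flip_concentration flip within-target partial correlation signs.
#' @param n1,n2,alpha,B,seed,tol,max_iter as in [null_study()].
#' @return object of class `alt_study` with per-run data and a `summary`
#'   (recovery rate, mean Jaccard).
#' @export
alt_study <- function(runs = 100, graph = default_pathway_graph(),
                      target_cliques = NULL, effect_sd = 5,
                      flip_concentration = TRUE,
                      n1 = 50, n2 = 50, alpha = 0.05, B = 500, seed = 1,
                      tol = 1e-8, max_iter = 5000) {
  jt <- prepare_jt(graph)
  if (is.null(target_cliques)) {
    ids <- names(jt$cliques)
    target_cliques <- ids[pmin(length(ids), c(2L, 3L))]
    target_cliques <- unique(target_cliques)
  }
  policy <- scoring_policy(alpha = alpha)
  seeds <- derive_run_seeds(seed, runs)
  rows <- vector("list", runs)
  for (i in seq_len(runs)) {
    rows[[i]] <- with_seed(seeds[i], {
      sc <- perturbed_scenario(graph, jt, target_cliques,
                               effect_sd = effect_sd,
                               flip_concentration = flip_concentration,
                               n1 = n1, n2 = n2)
      data <- sample_scenario(sc, seed = NULL)
      e <- perm_engine(data, jt, B = B, seed = NULL,
                       tol = tol, max_iter = max_iter)
      w <- stats::setNames(e$p[paste0("cc_", e$clique_ids)], e$clique_ids)
      rep <- mine_subpaths(jt, w, policy)
      if (length(rep$best)) {
        rs <- vapply(rep$best, `[[`, 0, "r_star")
        top <- rep$best[[which.max(rs)]]$cliques
      } else top <- character(0)
      jac <- length(intersect(top, target_cliques)) /
        length(union(top, target_cliques))
      data.frame(run = i, recovered = length(intersect(top, target_cliques)) > 0,
                 jaccard = jac, top_length = length(top))
    })
  }
  df <- do.call(rbind, rows)
  structure(list(runs = df,
                 summary = list(runs = runs,
                                target_cliques = target_cliques,
                                effect_sd = effect_sd,
                                recovery_rate = mean(df$recovered),
                                mean_jaccard = mean(df$jaccard))),
            class = "alt_study")
}

#' @export
print.alt_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "recovery study: %d runs, targets %s, effect %g sd\n",
    s$runs, paste(s$target_cliques, collapse = ","), s$effect_sd))
  cat(sprintf("recovery rate %.1f%%, mean Jaccard %.3f\n",
              100 * s$recovery_rate, s$mean_jaccard))
  invisible(x)
}
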