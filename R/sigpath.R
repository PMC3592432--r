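# Front end: the two-step pipeline over one or many pathways, returning a
# classed fit object with print / summary / plot methods, plus a writer for
# tab-separated report files.

#' Two-step topology-aware pathway analysis
#'
#' Step 1 tests, for every pathway, equality between the two phenotype
#' classes of the graph-constrained concentration matrices and of the mean
#' vectors (permutation-calibrated likelihood-ratio statistics on shrunken,
#' IPS-fitted graphical Gaussian models), with Bonferroni adjustment across
#' pathways within each test family. Step 2, on pathways passing the gating
#' rule, takes each clique's concentration-test p-value as its weight and
#' mines the junction tree for the signal sub-paths most associated with the
#' phenotype.
#'
#' Directed input graphs are preprocessed per pathway: self-loops removed,
#' remaining directed cycles broken by deleting the cycle edge with minimum
#' absolute expression correlation, the DAG moralized, the moral graph
#' triangulated, and one junction tree built per connected component
#' (components are analyzed as separate pathway components). The
#' heteroschedastic mean test is used when the pathway's concentration test
#' rejects at `alpha`, the homoschedastic one otherwise.
#'
#' @param data an [expression_dataset()], or a genes x samples matrix
#'   combined with `classes`.
#' @param graphs one `igraph` or a named list of `igraph`s (one per
#'   pathway); directed graphs allowed.
#' @param classes two-class labels, if `data` is a plain matrix.
#' @param alpha significance level for gating and clique meaningfulness.
#' @param t sub-path collapse threshold.
#' @param B permutations per pathway.
#' @param seed master seed; one sub-seed per pathway component is derived
#'   from it, so results are reproducible and independent of pathway order.
#' @param weight_source clique weights from the clique concentration test
#'   (default) or the clique mean test.
#' @param gating which adjusted p-values must fall below `alpha` before step
#'   2 runs: `"both"` (default), `"mean"`, `"concentration"`, or `"none"`
#'   (mine every pathway).
#' @param tol,max_iter IPS controls.
#' @return object of class `sigpath`: `pathways` (data.frame of step-1
#'   results), `subpaths` (data.frame of mined sub-paths), `reports`
#'   (per-component miner output and junction tree), `errors` (per-pathway
#'   isolated failures), `config`.
#' @export
sigpath <- function(data, graphs, classes = NULL, alpha = 0.05, t = 0.2,
                    B = 1000, seed = NULL,
                    weight_source = c("concentration", "mean"),
                    gating = c("both", "mean", "concentration", "none"),
                    tol = 1e-8, max_iter = 5000) {
  weight_source <- match.arg(weight_source)
  gating <- match.arg(gating)
  if (!inherits(data, "expression_dataset")) {
    if (is.null(classes)) stop("supply an expression_dataset or classes")
    data <- expression_dataset(data, classes)
  }
  if (igraph::is_igraph(graphs)) graphs <- list(pathway = graphs)
  if (is.null(names(graphs)) || any(!nzchar(names(graphs))))
    names(graphs) <- paste0("pathway", seq_along(graphs))

  # split every pathway into analyzable components first so seeds are stable
  units <- list()
  errors <- list()
  for (pw in names(graphs)) {
    res <- tryCatch({
      g <- assert_named_graph(graphs[[pw]])
      g <- restrict_to_measured(g, data)
      g <- remove_self_loops(g)
      if (igraph::is_directed(g)) {
        if (!igraph::is_dag(g)) g <- break_cycles(g, data)
        g <- moralize(g)
      }
      comp <- igraph::components(g)
      lapply(seq_len(comp$no), function(k) {
        sub <- igraph::induced_subgraph(
          g, names(comp$membership)[comp$membership == k])
        id <- if (comp$no == 1L) pw else paste0(pw, ".", k)
        list(id = id, pathway = pw, graph = sub)
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[pw]] <- conditionMessage(res)
      warning("pathway ", pw, " skipped: ", conditionMessage(res))
    } else units <- c(units, res)
  }
  if (!length(units)) stop("no analyzable pathway")

  unit_seeds <- if (is.null(seed)) rep(list(NULL), length(units))
                else as.list(derive_run_seeds(seed, length(units)))
  policy <- scoring_policy(alpha = alpha, t = t)

  rows <- list()
  engines <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    res <- tryCatch({
      tg <- triangulate_graph(u$graph)
      jt <- junction_tree(tg)
      e <- perm_engine(data, jt, B = B, seed = unit_seeds[[i]],
                       tol = tol, max_iter = max_iter)
      list(jt = jt, engine = e)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[u$id]] <- conditionMessage(res)
      warning("pathway ", u$id, " skipped: ", conditionMessage(res))
      next
    }
    e <- res$engine
    p_conc <- unname(e$p["concentration"])
    hetero <- p_conc < alpha
    p_mean <- unname(if (hetero) e$p["mean_hetero"] else e$p["mean_homo"])
    rows[[u$id]] <- data.frame(
      pathway = u$id, n_genes = length(unique(unlist(res$jt$cliques))),
      n_cliques = length(res$jt$cliques),
      stat_concentration = unname(e$observed["concentration"]),
      p_concentration = p_conc,
      mean_variant = if (hetero) "heteroschedastic" else "homoschedastic",
      stat_mean = unname(
        e$observed[if (hetero) "mean_hetero" else "mean_homo"]),
      p_mean = p_mean,
      stringsAsFactors = FALSE)
    engines[[u$id]] <- res
  }
  if (!length(rows)) stop("every pathway failed; first error: ",
                          errors[[1]])
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_concentration_adj <- bonferroni(tab$p_concentration)
  tab$p_mean_adj <- bonferroni(tab$p_mean)
  tab$selected <- switch(gating,
    both = tab$p_mean_adj < alpha & tab$p_concentration_adj < alpha,
    mean = tab$p_mean_adj < alpha,
    concentration = tab$p_concentration_adj < alpha,
    none = rep(TRUE, nrow(tab)))

  reports <- list()
  sp_rows <- list()
  for (id in tab$pathway[tab$selected]) {
    res <- engines[[id]]
    e <- res$engine
    pref <- if (weight_source == "concentration") "cc_" else "cm_"
    w <- stats::setNames(e$p[paste0(pref, e$clique_ids)], e$clique_ids)
    rep <- mine_subpaths(res$jt, w, policy)
    reports[[id]] <- list(jt = res$jt, weights = w, report = rep)
    for (sp in rep$subpaths) {
      sp_rows[[length(sp_rows) + 1L]] <- data.frame(
        pathway = id, path = sp$path,
        cliques = paste(sp$cliques, collapse = "|"),
        genes = paste(sp$genes, collapse = "|"),
        l = sp$l, r = sp$r, m = sp$m, r_star = sp$r_star,
        cluster = sp$cluster, representative = sp$representative,
        stringsAsFactors = FALSE)
    }
  }
  subpaths <- if (length(sp_rows)) do.call(rbind, sp_rows)
  else data.frame(pathway = character(0), path = character(0),
                  cliques = character(0), genes = character(0),
                  l = integer(0), r = numeric(0), m = integer(0),
                  r_star = numeric(0), cluster = integer(0),
                  representative = logical(0))
  structure(list(
    pathways = tab, subpaths = subpaths, reports = reports,
    errors = errors,
    config = list(alpha = alpha, t = t, B = B, seed = seed,
                  weight_source = weight_source, gating = gating,
                  tol = tol, max_iter = max_iter,
                  n1 = data$n1, n2 = data$n2,
                  classes = levels(data$classes))),
    class = "sigpath")
}

#' @export
print.sigpath <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "sigpath fit: %d pathway component(s), %d vs %d samples, B = %d\n",
    nrow(x$pathways), cfg$n1, cfg$n2, cfg$B))
  sel <- sum(x$pathways$selected)
  cat(sprintf("selected for signal-path mining (gating '%s'): %d\n",
              cfg$gating, sel))
  if (nrow(x$subpaths)) {
    reps <- x$subpaths[x$subpaths$representative, , drop = FALSE]
    cat(sprintf("representative sub-paths: %d\n", nrow(reps)))
  }
  if (length(x$errors))
    cat("pathways skipped:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sigpath <- function(object, ...) {
  structure(list(fit = object), class = "summary.sigpath")
}

#' @export
print.summary.sigpath <- function(x, ...) {
  print(x$fit)
  tab <- x$fit$pathways
  show <- tab[, c("pathway", "n_genes", "n_cliques", "p_mean_adj",
                  "p_concentration_adj", "selected")]
  cat("\nStep 1 (Bonferroni-adjusted p-values):\n")
  print(show, row.names = FALSE, digits = 4)
  reps <- x$fit$subpaths[x$fit$subpaths$representative, , drop = FALSE]
  if (nrow(reps)) {
    cat("\nStep 2 representative sub-paths:\n")
    print(reps[, c("pathway", "cliques", "l", "r_star")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Plot the junction tree of an analyzed pathway
#'
#' Cliques with meaningful weights are filled; cliques on the top relevant
#' sub-path get a heavier border.
#'
#' @param x a [sigpath()] fit.
#' @param pathway pathway id (default: first mined pathway).
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.sigpath <- function(x, pathway = NULL, ...) {
  if (!length(x$reports)) stop("no pathway passed the gating rule; nothing to plot")
  pathway <- pathway %||% names(x$reports)[1]
  rep <- x$reports[[pathway]]
  if (is.null(rep)) stop("pathway not mined: ", pathway)
  g <- jt_igraph(rep$jt)
  meaningful <- rep$weights[igraph::V(g)$name] < x$config$alpha
  top <- character(0)
  if (length(rep$report$best)) {
    rs <- vapply(rep$report$best, `[[`, 0, "r_star")
    top <- rep$report$best[[which.max(rs)]]$cliques
  }
  igraph::plot.igraph(
    g,
    vertex.color = ifelse(meaningful, "tomato", "grey90"),
    vertex.frame.color = ifelse(igraph::V(g)$name %in% top, "black", "grey60"),
    vertex.frame.width = ifelse(igraph::V(g)$name %in% top, 3, 1),
    vertex.label = paste0(igraph::V(g)$name, "\n",
                          signif(rep$weights[igraph::V(g)$name], 2)),
    vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Write report tables of a fit
#'
#' Writes `pathways.tsv` and `subpaths.tsv` (tab-separated, with a commented
#' header block echoing the configuration) plus `run.log`. Re-running with
#' the same seed reproduces the files byte for byte.
#'
#' @param x a [sigpath()] fit.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_sigpath <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- x$config
  hdr <- c(
    sprintf("# sigpath %s", as.character(utils::packageVersion("sigpath"))),
    sprintf("# alpha=%g t=%g B=%d seed=%s", cfg$alpha, cfg$t, cfg$B,
            if (is.null(cfg$seed)) "NULL" else cfg$seed),
    sprintf("# weight_source=%s gating=%s", cfg$weight_source, cfg$gating),
    sprintf("# classes=%s n1=%d n2=%d", paste(cfg$classes, collapse = "/"),
            cfg$n1, cfg$n2))
  wr <- function(df, file) {
    con <- file.path(dir, file)
    writeLines(hdr, con)
    suppressWarnings(utils::write.table(
      df, con, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
    con
  }
  p1 <- wr(x$pathways, "pathways.tsv")
  p2 <- wr(x$subpaths, "subpaths.tsv")
  log <- c(hdr, sprintf("# pathways=%d mined=%d subpaths=%d",
                        nrow(x$pathways), length(x$reports),
                        nrow(x$subpaths)),
           if (length(x$errors))
             paste0("# skipped ", names(x$errors), ": ",
                    unlist(x$errors)))
  writeLines(log, file.path(dir, "run.log"))
  invisible(c(p1, p2, file.path(dir, "run.log")))
}
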