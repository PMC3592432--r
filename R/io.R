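# Readers for expression matrices, class label files and pathway graphs
# (GraphML / SIF / two-column edge list), plus dataset-graph reconciliation.

#' Read an expression matrix and class labels from files
#'
#' The expression file is TSV/CSV with gene identifiers in the first column
#' and sample identifiers in the header; the label file has two columns
#' (sample identifier, class), no header required.
#'
#' @param path expression file.
#' @param labels_path two-column sample/class file.
#' @param sep field separator (guessed from the extension by default:
#'   `","` for `.csv`, tab otherwise).
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path, labels_path, sep = NULL) {
  pick_sep <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  sep <- sep %||% pick_sep(path)
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) stop("duplicated gene row(s): ", paste(dup, collapse = ", "))
  x <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(x)) stop("non-numeric expression values in ", path)
  rownames(x) <- genes
  lab <- utils::read.delim(labels_path, sep = pick_sep(labels_path),
                           header = FALSE, stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) stop("label file needs two columns: sample, class")
  # tolerate a header line
  if (!any(lab[[1]] %in% colnames(x)) && nrow(lab) > 1L) lab <- lab[-1, ]
  cls <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  miss <- setdiff(colnames(x), names(cls))
  if (length(miss)) stop("samples without class label: ",
                         paste(miss, collapse = ", "))
  expression_dataset(x, cls[colnames(x)])
}

#' Read a pathway graph
#'
#' Supported formats: GraphML (via igraph), SIF (`source interaction target
#' [target ...]`; interaction types kept as an edge attribute but ignored by
#' the analysis), and a two-column whitespace-separated edge list. Duplicate
#' edges are collapsed (with a message) and the graph is returned directed.
#'
#' @param path graph file.
#' @param format one of `"graphml"`, `"sif"`, `"edgelist"` (guessed from the
#'   extension by default).
#' @return directed `igraph` with named vertices.
#' @export
read_pathway_graph <- function(path,
                               format = c("auto", "graphml", "sif",
                                          "edgelist")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
    else if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif"
    else "edgelist"
  }
  g <- switch(format,
    graphml = {
      gg <- igraph::read_graph(path, format = "graphml")
      if (!igraph::is_directed(gg)) gg <- igraph::as_directed(gg, mode = "arbitrary")
      gg
    },
    sif = {
      lines <- readLines(path)
      lines <- lines[nzchar(trimws(lines))]
      if (!length(lines)) stop("empty graph file: ", path)
      rows <- lapply(strsplit(lines, "[\t ]+"), function(f) {
        if (length(f) == 1L) return(cbind(from = f, type = NA, to = NA))
        if (length(f) < 3L) stop("malformed SIF line: ", paste(f, collapse = " "))
        cbind(from = f[1], type = f[2], to = f[-(1:2)])
      })
      el <- do.call(rbind, rows)
      iso <- el[is.na(el[, "to"]), "from"]
      el <- el[!is.na(el[, "to"]), , drop = FALSE]
      ndup <- sum(duplicated(el[, c("from", "to")]))
      if (ndup) message(ndup, " duplicate SIF edge(s) collapsed")
      keep <- !duplicated(el[, c("from", "to")])
      el <- el[keep, , drop = FALSE]
      gg <- igraph::graph_from_data_frame(
        data.frame(from = el[, "from"], to = el[, "to"],
                   interaction = el[, "type"], stringsAsFactors = FALSE),
        directed = TRUE)
      if (length(iso)) gg <- igraph::add_vertices(gg, length(iso),
                                                  name = iso)
      gg
    },
    edgelist = {
      tab <- utils::read.table(path, header = FALSE,
                               stringsAsFactors = FALSE)
      if (ncol(tab) < 2L) stop("edge list needs two columns")
      ndup <- sum(duplicated(tab[, 1:2]))
      if (ndup) message(ndup, " duplicate edge(s) collapsed")
      igraph::graph_from_data_frame(unique(tab[, 1:2]), directed = TRUE)
    })
  if (igraph::vcount(g) == 0L) stop("empty graph: ", path)
  assert_named_graph(g)
  g
}

#' Restrict a pathway graph to measured genes
#'
#' Drops graph nodes without an expression row (with their edges) and warns
#' listing the dropped genes, mirroring how array coverage implicitly trims
#' curated pathways.
#'
#' @param g `igraph` with named vertices.
#' @param data an [expression_dataset()].
#' @return the induced subgraph on measured genes.
#' @export
restrict_to_measured <- function(g, data) {
  assert_named_graph(g)
  data <- as_expression_dataset(data)
  drop <- setdiff(igraph::V(g)$name, rownames(data$x))
  if (length(drop) == igraph::vcount(g))
    stop("no graph gene is measured in the expression data")
  if (length(drop)) {
    warning("dropping unmeasured gene(s): ", paste(drop, collapse = ", "))
    g <- igraph::delete_vertices(g, drop)
  }
  g
}
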