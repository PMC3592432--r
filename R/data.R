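#' Two-class expression dataset
#'
#' Container for a genes x samples expression matrix with a binary phenotype.
#' Values are assumed already normalized (log scale for microarrays,
#' variance-stabilized counts for RNA-seq); the graphical Gaussian machinery
#' works on whatever continuous scale is supplied.
#'
#' @param x numeric matrix, genes in rows (unique rownames required), samples
#'   in columns.
#' @param classes factor/character/vector of length `ncol(x)` with exactly two
#'   levels; at least 3 samples per class.
#' @return object of class `expression_dataset` with elements `x`, `classes`
#'   (factor), `n1`, `n2`, `P`.
#' @export
expression_dataset <- function(x, classes) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (anyNA(x)) stop("expression matrix contains missing values")
  if (is.null(rownames(x))) stop("expression matrix must have gene rownames")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) stop("duplicated gene identifiers: ",
                        paste(unique(dup), collapse = ", "))
  classes <- as.factor(as.vector(classes))
  if (length(classes) != ncol(x))
    stop("class labels (", length(classes), ") do not match samples (",
         ncol(x), ")")
  if (nlevels(classes) != 2L) stop("two classes required, found ",
                                   nlevels(classes))
  n <- table(classes)
  if (any(n < 3L)) stop("each class needs at least 3 samples (have ",
                        paste(n, collapse = "/"), ")")
  structure(list(x = x, classes = classes,
                 n1 = as.integer(n[1]), n2 = as.integer(n[2]),
                 P = nrow(x)),
            class = "expression_dataset")
}

as_expression_dataset <- function(x) {
  if (inherits(x, "expression_dataset")) return(x)
  stop("expected an expression_dataset (see ?expression_dataset)")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%s: %d, %s: %d)\n",
              x$P, ncol(x$x), levels(x$classes)[1], x$n1,
              levels(x$classes)[2], x$n2))
  invisible(x)
}

split_by_class <- function(data) {
  lv <- levels(data$classes)
  list(x1 = data$x[, data$classes == lv[1], drop = FALSE],
       x2 = data$x[, data$classes == lv[2], drop = FALSE])
}
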