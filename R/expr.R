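#' Two-group miRNA expression matrix
#'
#' Light container for a log2 expression matrix (rows = miRNAs, columns =
#' samples) with a two-level group factor, as produced by an RMA-normalized
#' microarray experiment. This is the substrate of candidate selection and
#' reference-gene stability scoring.
#'
#' @param values Numeric matrix of log2 intensities with rownames (miRNA ids)
#'   and colnames (sample ids). All values must be finite.
#' @param groups Character or factor vector of group labels, one per sample,
#'   named by sample id (or in column order). Exactly two distinct levels are
#'   required; by convention `"B"` (borderline, negative class) and `"M"`
#'   (malignant, positive class).
#' @return An object of class `mir_expr`: a list with elements `values`
#'   (the matrix) and `groups` (a named factor aligned to `colnames(values)`).
#' @examples
#' m <- matrix(rnorm(12, 8), 2, 6,
#'             dimnames = list(c("miR-a", "miR-b"), paste0("s", 1:6)))
#' x <- mir_expr(m, rep(c("B", "M"), each = 3))
#' group_means(x)
#' @export
mir_expr <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have miRNA rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate miRNA ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  groups <- as.factor(groups)
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("samples without a group label: ", paste(missing, collapse = ", "))
    groups <- groups[colnames(values)]
  } else {
    if (length(groups) != ncol(values))
      stop("`groups` must have one label per sample")
    names(groups) <- colnames(values)
  }
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L)
    stop("`groups` must have exactly two levels, got ", nlevels(groups))
  structure(list(values = values, groups = groups), class = "mir_expr")
}

#' @export
print.mir_expr <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("<mir_expr> %d miRNAs x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.mir_expr <- function(x) dim(x$values)

#' Per-group mean log2 expression
#'
#' @param x A [mir_expr] object.
#' @return Numeric matrix, one row per miRNA, one column per group level,
#'   holding the arithmetic mean of log2 values (i.e. the log2 of the
#'   geometric mean on the linear scale).
#' @export
group_means <- function(x) {
  stopifnot(inherits(x, "mir_expr"))
  lv <- levels(x$groups)
  out <- matrix(NA_real_, nrow(x$values), length(lv),
                dimnames = list(rownames(x$values), lv))
  for (g in lv)
    out[, g] <- rowMeans(x$values[, x$groups == g, drop = FALSE])
  out
}

#' Subset a mir_expr by miRNA and/or sample
#'
#' @param x A [mir_expr].
#' @param mirnas Optional character vector of miRNA ids to keep.
#' @param samples Optional character vector of sample ids to keep.
#' @return A [mir_expr] restricted to the requested rows/columns.
#' @export
subset_expr <- function(x, mirnas = NULL, samples = NULL) {
  stopifnot(inherits(x, "mir_expr"))
  v <- x$values
  if (!is.null(mirnas)) {
    bad <- setdiff(mirnas, rownames(v))
    if (length(bad)) stop("unknown miRNA id(s): ", paste(bad, collapse = ", "))
    v <- v[mirnas, , drop = FALSE]
  }
  g <- x$groups
  if (!is.null(samples)) {
    bad <- setdiff(samples, colnames(v))
    if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))
    v <- v[, samples, drop = FALSE]
    g <- g[samples]
  }
  mir_expr(v, g)
}
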