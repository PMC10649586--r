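#' Read / write the expression TSV format
#'
#' Tab-delimited, first column `mirna_id`, one column per sample, log2 values.
#'
#' @param path File path.
#' @param groups Optional named group vector/factor to attach (making the
#'   result a [mir_expr]); otherwise a plain matrix is returned.
#' @return A [mir_expr] (if `groups` given) or a numeric matrix.
#' @export
read_expression_tsv <- function(path, groups = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "mirna_id")
    stop("first column must be `mirna_id`, got `", names(df)[1], "`")
  if (anyDuplicated(df$mirna_id))
    stop("duplicate miRNA ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- df$mirna_id
  if (is.null(groups)) m else mir_expr(m, groups)
}

#' @rdname read_expression_tsv
#' @param x A [mir_expr] or matrix with dimnames.
#' @export
write_expression_tsv <- function(x, path) {
  m <- if (inherits(x, "mir_expr")) x$values else x
  df <- data.frame(mirna_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample-groups TSV (`sample_id`, `group`)
#'
#' @param path File path.
#' @param samples Optional sample ids that must all be present; an informative
#'   error names any sample missing a group.
#' @return Named factor of groups.
#' @export
read_groups_tsv <- function(path, samples = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("groups file needs columns `sample_id`, `group`")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  g <- factor(df$group)
  names(g) <- df$sample_id
  if (!is.null(samples)) {
    miss <- setdiff(samples, names(g))
    if (length(miss))
      stop("no group for sample(s): ", paste(miss, collapse = ", "))
    extra <- setdiff(names(g), samples)
    if (length(extra))
      stop("unknown sample(s) in groups file: ", paste(extra, collapse = ", "))
    g <- g[samples]
  }
  g
}

#' @rdname read_groups_tsv
#' @param groups Named factor/vector of group labels.
#' @export
write_groups_tsv <- function(groups, path) {
  utils::write.table(data.frame(sample_id = names(groups),
                                group = as.character(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the long-format Cq TSV
#'
#' Columns `sample_id`, `mirna_id`, `replicate`, `cq`.
#'
#' @param path File path.
#' @return Data.frame in the long Cq format.
#' @export
read_cq_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "mirna_id", "replicate", "cq")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Cq file missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_cq_tsv
#' @param cq Long-format Cq data.frame.
#' @export
write_cq_tsv <- function(cq, path) {
  utils::write.table(cq, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-availability list (one miRNA id per line)
#'
#' @param path File path; blank lines and `#` comments ignored.
#' @return Character vector of ids.
#' @export
read_probe_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Minimal GEO series-matrix reader
#'
#' Extracts only the tab-delimited expression block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` of a GEO
#' series-matrix file. Metadata lines are ignored; full SOFT parsing is out
#' of scope.
#'
#' @param path Path to a (decompressed) series-matrix text file.
#' @return Numeric matrix, rows = probe/miRNA ids, columns = GSM sample ids.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1)
    stop("no series-matrix table block found in ", path)
  block <- lines[(beg + 1):(end - 1)]
  df <- utils::read.delim(text = block, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- gsub('^"|"$', "", df[[1]])
  colnames(m) <- gsub('^"|"$', "", colnames(m))
  storage.mode(m) <- "double"
  m
}

#' Write the simulation ground truth as JSON
#'
#' @param x A simulated [mir_expr] or `cq_table` carrying a `truth` attribute.
#' @param path Output path.
#' @export
write_truth_json <- function(x, path) {
  tr <- attr(x, "truth")
  if (is.null(tr)) stop("object carries no ground-truth attribute")
  jsonlite::write_json(
    list(seed = tr$seed,
         de_up = as.list(tr$de_up), de_down = as.list(tr$de_down),
         normalizer_ids = tr$normalizer_ids,
         sample_offsets = as.list(tr$offsets)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
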