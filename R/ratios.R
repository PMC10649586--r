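#' Build all up/down miRNA expression ratios
#'
#' For every (up, down) combination of an up-regulated and a down-regulated
#' miRNA, computes the per-sample linear-scale quotient
#' `value_up / value_down` (equivalently `2^(Cq_down - Cq_up)`). Because the
#' reference Cq cancels in the quotient, ratios are invariant to the
#' normalizer set — the property that motivates the ratio design.
#'
#' @param rel A [delta_cq()] result, or a samples x miRNA matrix of positive
#'   linear-scale expression values.
#' @param up Character vector of up-regulated miRNA ids.
#' @param down Character vector of down-regulated ids (disjoint from `up`).
#' @return A list of class `ratio_matrix`: `values` (samples x ratios matrix,
#'   ratio ids `"up/down"`), `info` (data.frame `ratio_id`, `up`, `down`).
#' @examples
#' m <- matrix(c(8, 2, 4, 1), 2, 2, dimnames = list(c("s1", "s2"), c("u", "d")))
#' build_ratios(m, "u", "d")$values
#' @export
build_ratios <- function(rel, up, down) {
  if (inherits(rel, "rel_expr")) rel <- rel$rel
  stopifnot(is.matrix(rel))
  if (length(intersect(up, down)))
    stop("up and down sets must be disjoint")
  bad <- setdiff(c(up, down), colnames(rel))
  if (length(bad)) stop("unmeasured miRNA id(s): ", paste(bad, collapse = ", "))
  if (any(rel <= 0, na.rm = TRUE)) stop("expression values must be positive")
  info <- expand.grid(down = down, up = up, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, c("up", "down")]
  info$ratio_id <- paste(info$up, info$down, sep = "/")
  vals <- rel[, info$up, drop = FALSE] / rel[, info$down, drop = FALSE]
  colnames(vals) <- info$ratio_id
  structure(list(values = vals,
                 info = info[, c("ratio_id", "up", "down")]),
            class = "ratio_matrix")
}

#' ROC curve with the M-high orientation
#'
#' Thresholds are placed at midpoints of consecutive sorted unique values plus
#' +/-Inf; at a threshold `t`, sensitivity is the fraction of M samples with
#' value strictly above `t` and specificity the fraction of B samples at or
#' below `t`. The AUC is the trapezoid area over the full curve, which equals
#' the rank statistic (fraction of (M, B) pairs with the M value higher, ties
#' counted one half). Orientation is never auto-flipped: a marker that is
#' M-low yields an AUC below 0.5, reported as-is.
#'
#' @param values Numeric per-sample values (e.g. one ratio's column).
#' @param groups Two-level factor (levels `B`, `M`); M is the positive class.
#' @return A list of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `youden` (J at each threshold), `auc`.
#' @examples
#' r <- roc_curve(c(1, 2, 3, 4, 5, 6), factor(rep(c("B", "M"), each = 3)))
#' r$auc  # 1
#' @export
roc_curve <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  is_m <- groups == "M"
  if (!any(is_m) || all(is_m)) stop("both groups must be present")
  thr <- threshold_grid(values)
  sens <- vapply(thr, function(t) mean(values[is_m] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(values[!is_m] <= t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 youden = sens + spec - 1, auc = auc),
            class = "roc_result")
}

#' Youden-index optimal operating point
#'
#' Picks the threshold maximizing `J = sensitivity + specificity - 1`.
#' Ties break toward higher specificity, then toward the lower threshold.
#'
#' @param roc A [roc_curve()] result.
#' @return List: `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  ord <- order(-roc$youden, -roc$specificity, roc$thresholds)
  i <- ord[1]
  list(threshold = roc$thresholds[i], J = roc$youden[i],
       sensitivity = roc$sensitivity[i], specificity = roc$specificity[i])
}

#' Per-ratio differential tests and ROC summaries
#'
#' Equal-variance two-sample t-test on the log2 ratios (two-sided, B-minus-M
#' sign convention), plus the ROC/AUC and Youden-optimal operating point of
#' each ratio. No multiplicity adjustment is applied by default; a
#' Benjamini-Hochberg column can be requested.
#'
#' @param ratios A [build_ratios()] result.
#' @param groups Named two-level factor (levels `B`, `M`) covering the samples.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param adjust If `TRUE`, add a BH-adjusted p-value column `p_bh`.
#' @return Data.frame, one row per ratio: `ratio_id`, `up`, `down`, `t`, `p`,
#'   `significant`, `auc`, `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
test_ratios <- function(ratios, groups, alpha = 0.05, adjust = FALSE) {
  stopifnot(inherits(ratios, "ratio_matrix"))
  groups <- as.factor(groups)
  samples <- rownames(ratios$values)
  if (!is.null(names(groups))) groups <- groups[samples]
  out <- ratios$info
  stats_list <- lapply(seq_len(ncol(ratios$values)), function(j) {
    v <- ratios$values[, j]
    dt <- differential_test(v, groups, log2_transform = TRUE)
    roc <- roc_curve(v, groups)
    opt <- youden_optimal(roc)
    c(t = dt$t, p = dt$p, auc = roc$auc, threshold = opt$threshold,
      J = opt$J, sensitivity = opt$sensitivity, specificity = opt$specificity)
  })
  st <- do.call(rbind, stats_list)
  out <- cbind(out, as.data.frame(st))
  out$significant <- out$p < alpha
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  row.names(out) <- NULL
  out
}
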