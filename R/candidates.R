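#' Log2 fold-change of one miRNA between groups
#'
#' Difference of mean log2 expression, M minus B — equivalently the log2 of
#' the ratio of linear-scale geometric means.
#'
#' @param x A [mir_expr].
#' @param mirna_id Single miRNA id.
#' @return Numeric log2 fold-change (positive = higher in M).
#' @examples
#' m <- matrix(c(4, 5, 6, 8, 9, 10), 1, 6,
#'             dimnames = list("miR-a", paste0("s", 1:6)))
#' log2_fold_change(mir_expr(m, rep(c("B", "M"), each = 3)), "miR-a")  # +4
#' @export
log2_fold_change <- function(x, mirna_id) {
  stopifnot(inherits(x, "mir_expr"), length(mirna_id) == 1)
  if (!mirna_id %in% rownames(x$values))
    stop("unknown miRNA id: ", mirna_id)
  gm <- group_means(subset_expr(x, mirnas = mirna_id))
  unname(gm[1, "M"] - gm[1, "B"])
}

# Internal: one candidate row per miRNA with means, FC, direction, errors.
candidate_frame <- function(x) {
  gm <- group_means(x)
  fc <- gm[, "M"] - gm[, "B"]
  dir <- ifelse(fc >= 0, "up", "down")
  nerr <- vapply(rownames(x$values), function(id)
    classification_errors(x$values[id, ], x$groups, direction = dir[id]),
    integer(1))
  data.frame(mirna_id = rownames(x$values),
             direction = dir,
             mean_expr_B = unname(gm[, "B"]),
             mean_expr_M = unname(gm[, "M"]),
             log2_fold_change = unname(fc),
             n_errors = unname(nerr),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stringent candidate selection
#'
#' First-pass selection of differentially expressed miRNAs: keep those with
#' an absolute fold-change of at least `min_factor` (linear scale, so
#' `|log2FC| >= log2(min_factor)`, boundary included) AND mean log2 expression
#' above `expr_min` in at least one group.
#'
#' @param x A [mir_expr].
#' @param expr_min Log2 expression threshold (strict `>`, default 5).
#' @param min_factor Minimum linear fold-change (default 2).
#' @return A data.frame of class `mir_candidates` with per-miRNA means,
#'   log2 fold-change, direction, best single-threshold error count and a
#'   `filter` provenance column (`"stringent"`).
#' @examples
#' x <- simulate_microarray(group_design(3, 3), sim_params(n_mirnas = 60, seed = 5))
#' head(select_stringent(x))
#' @export
select_stringent <- function(x, expr_min = 5, min_factor = 2) {
  stopifnot(inherits(x, "mir_expr"))
  if (min_factor <= 0) stop("min_factor must be positive")
  cf <- candidate_frame(x)
  keep <- abs(cf$log2_fold_change) >= log2(min_factor) &
    (cf$mean_expr_B > expr_min | cf$mean_expr_M > expr_min)
  out <- cf[keep, , drop = FALSE]
  out$filter <- rep("stringent", nrow(out))
  row.names(out) <- NULL
  class(out) <- c("mir_candidates", "data.frame")
  out
}

#' Fold-change-only complementary selection
#'
#' Second-pass selection focused on one direction (default: up-regulated),
#' using only a strict fold-change criterion (`|log2FC| > log2(min_factor)`)
#' with no expression filter, excluding miRNAs already selected.
#'
#' @param x A [mir_expr].
#' @param min_factor Minimum linear fold-change, strict (default 2).
#' @param direction `"up"` (default) or `"down"`.
#' @param exclude A `mir_candidates` set (typically the stringent set) whose
#'   ids must not be re-selected.
#' @return A `mir_candidates` data.frame with `filter = "fc_only"`.
#' @export
select_fc_only <- function(x, min_factor = 2, direction = c("up", "down"),
                           exclude = NULL) {
  stopifnot(inherits(x, "mir_expr"))
  direction <- match.arg(direction)
  if (min_factor <= 0) stop("min_factor must be positive")
  cf <- candidate_frame(x)
  keep <- cf$direction == direction &
    abs(cf$log2_fold_change) > log2(min_factor)
  if (!is.null(exclude)) keep <- keep & !(cf$mirna_id %in% exclude$mirna_id)
  out <- cf[keep, , drop = FALSE]
  out$filter <- rep("fc_only", nrow(out))
  row.names(out) <- NULL
  class(out) <- c("mir_candidates", "data.frame")
  out
}

#' Best single-threshold resubstitution error count
#'
#' Minimum number of misclassified samples over all cut-points of a
#' one-dimensional threshold classifier. For an up-oriented marker the rule is
#' "call M if value > t" (a value equal to the threshold is called B); for a
#' down-oriented marker the orientation is reversed. Thresholds are enumerated
#' at midpoints of consecutive sorted unique values plus +/-Inf, which covers
#' every distinct classification the rule can produce.
#'
#' @param values Numeric vector of per-sample measurements.
#' @param groups Two-level factor (levels `B`, `M`) aligned with `values`.
#' @param direction `"up"` (M-high) or `"down"` (M-low).
#' @return Integer error count in `[0, min(n_B, n_M)]`.
#' @examples
#' classification_errors(c(1, 2, 3, 4, 5, 6),
#'                       factor(rep(c("B", "M"), each = 3)))  # 0
#' @export
classification_errors <- function(values, groups, direction = c("up", "down")) {
  direction <- match.arg(direction)
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) == 2)
  if (direction == "down") values <- -values
  is_m <- groups == "M"
  if (!any(is_m) || all(is_m)) stop("both groups must be present")
  thr <- threshold_grid(values)
  errs <- vapply(thr, function(t) {
    pred_m <- values > t
    sum(pred_m != is_m)
  }, numeric(1))
  as.integer(min(errs))
}

# Midpoints of consecutive sorted unique values, plus -Inf / +Inf.
threshold_grid <- function(values) {
  u <- sort(unique(values))
  mid <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  c(-Inf, mid, Inf)
}

#' Flag candidates by the group-mean expression rule
#'
#' Marks candidates whose mean log2 expression exceeds `expr_B_min` in the
#' borderline group OR `expr_M_min` in the malignant group (the rule is a
#' disjunction). Thresholds are configurable; the default malignant-group
#' threshold of 20 log2 is far above plausible RMA intensities and acts as a
#' B-group-only rule unless lowered.
#'
#' @param candidates A `mir_candidates` data.frame.
#' @param expr_B_min Borderline-group mean log2 threshold (default 5).
#' @param expr_M_min Malignant-group mean log2 threshold (default 20).
#' @return The candidates with a logical `expression_rule` column added.
#' @export
apply_expression_rule <- function(candidates, expr_B_min = 5, expr_M_min = 20) {
  stopifnot(is.data.frame(candidates))
  candidates$expression_rule <- candidates$mean_expr_B > expr_B_min |
    candidates$mean_expr_M > expr_M_min
  candidates
}

#' Flag candidates by PCR-probe availability
#'
#' Records, for each candidate, whether a PCR probe is available; both the
#' flagged table and the retained subset view are accessible (nothing is
#' silently dropped).
#'
#' @param candidates A `mir_candidates` data.frame.
#' @param probe_list Character vector of miRNA ids with an available probe.
#' @param keep_only If `TRUE`, return only candidates with a probe; default
#'   `FALSE` returns all rows with a `probe_available` flag.
#' @return Candidates with a logical `probe_available` column (subset if
#'   `keep_only`).
#' @export
filter_probe_available <- function(candidates, probe_list, keep_only = FALSE) {
  stopifnot(is.data.frame(candidates))
  if (length(probe_list) == 0)
    warning("empty probe list: all candidates flagged unavailable")
  candidates$probe_available <- candidates$mirna_id %in% probe_list
  if (keep_only) {
    candidates <- candidates[candidates$probe_available, , drop = FALSE]
    row.names(candidates) <- NULL
  }
  candidates
}
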