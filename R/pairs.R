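#' Enumerate admissible pairs of ratios
#'
#' All unordered pairs of distinct ratios whose union of constituent miRNAs
#' has at least `min_distinct` members. For ratios of the form up/down this
#' means the two ratios share no miRNA. With `a` up- and `b` down-regulated
#' miRNAs the admissible count has the closed form
#' `choose(a*b, 2) - a*choose(b, 2) - b*choose(a, 2)` (all pairs minus those
#' sharing the up or the down member) — 900 for a 5 x 10 design.
#'
#' @param ratios A [build_ratios()] result (or its `info` data.frame).
#' @param min_distinct Minimum number of distinct miRNAs across the pair
#'   (default 4). Values above 4 leave no admissible pair (each pair involves
#'   at most 4 miRNAs) and trigger a warning.
#' @return Data.frame with columns `ratio_1`, `ratio_2` (ratio ids,
#'   `ratio_1 < ratio_2` by column order) and `n_distinct`.
#' @examples
#' m <- matrix(1:8 + 0, 2, 4,
#'             dimnames = list(c("s1", "s2"), c("u1", "u2", "d1", "d2")))
#' r <- build_ratios(m, c("u1", "u2"), c("d1", "d2"))
#' nrow(enumerate_ratio_pairs(r))  # 2
#' @export
enumerate_ratio_pairs <- function(ratios, min_distinct = 4) {
  info <- if (inherits(ratios, "ratio_matrix")) ratios$info else ratios
  stopifnot(all(c("ratio_id", "up", "down") %in% names(info)))
  n <- nrow(info)
  if (min_distinct > 4)
    warning("each pair of up/down ratios involves at most 4 distinct miRNAs; ",
            "min_distinct > 4 admits none")
  if (n < 2) return(data.frame(ratio_1 = character(), ratio_2 = character(),
                               n_distinct = integer()))
  idx <- utils::combn(n, 2)
  nd <- vapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    length(unique(c(info$up[i], info$down[i], info$up[j], info$down[j])))
  }, integer(1))
  keep <- nd >= min_distinct
  data.frame(ratio_1 = info$ratio_id[idx[1, keep]],
             ratio_2 = info$ratio_id[idx[2, keep]],
             n_distinct = nd[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Closed-form admissible pair count
#'
#' @param a Number of up-regulated miRNAs.
#' @param b Number of down-regulated miRNAs.
#' @return `choose(a*b, 2) - a*choose(b, 2) - b*choose(a, 2)`.
#' @examples
#' pair_count(5, 10)  # 900
#' @export
pair_count <- function(a, b) {
  choose(a * b, 2) - a * choose(b, 2) - b * choose(a, 2)
}

#' Classify samples with a thresholded pair of ratios
#'
#' Combines the two single-ratio Youden thresholds into one call per sample.
#' Rules: `"AND"` (default) predicts M iff both ratio values strictly exceed
#' their thresholds (the conservative malignant-quadrant reading); `"OR"`
#' predicts M if either does; `"SUM"` predicts M iff the summed log2 excess
#' `(log2 v1 - log2 t1) + (log2 v2 - log2 t2)` is positive. A sample on a
#' threshold is never called M (strict `>`).
#'
#' @param v1,v2 Per-sample values of the two ratios.
#' @param t1,t2 Their Youden-optimal thresholds.
#' @param rule `"AND"`, `"OR"` or `"SUM"`.
#' @return Factor of predicted labels (`B`/`M`), `NA` where a value is missing.
#' @export
classify_pair <- function(v1, v2, t1, t2, rule = c("AND", "OR", "SUM")) {
  rule <- match.arg(rule)
  pred <- switch(rule,
    AND = v1 > t1 & v2 > t2,
    OR  = v1 > t1 | v2 > t2,
    SUM = (log2(v1) - log2(t1)) + (log2(v2) - log2(t2)) > 0)
  factor(ifelse(pred, "M", "B"), levels = c("B", "M"))
}

#' Classification-error matrix over all admissible pairs
#'
#' For each admissible pair of ratios, classifies every sample with the two
#' fixed single-ratio Youden thresholds combined under `rule`, and counts
#' misclassifications against the true labels (resubstitution error, as when
#' thresholds and errors are read from the same cohort). Thresholds are those
#' of the single-ratio step; they are not re-optimized per pair.
#'
#' @param ratios A [build_ratios()] result.
#' @param groups Named two-level factor (levels `B`, `M`).
#' @param rule Combination rule, see [classify_pair()].
#' @param min_distinct Passed to [enumerate_ratio_pairs()].
#' @return A list of class `pair_error_matrix`: `pairs` (data.frame `ratio_1`,
#'   `ratio_2`, `errors`, `n_classified`), `thresholds` (named per-ratio
#'   Youden thresholds), `rule`, `n_samples`.
#' @export
pair_error_matrix <- function(ratios, groups, rule = c("AND", "OR", "SUM"),
                              min_distinct = 4) {
  stopifnot(inherits(ratios, "ratio_matrix"))
  rule <- match.arg(rule)
  groups <- as.factor(groups)
  samples <- rownames(ratios$values)
  if (!is.null(names(groups))) groups <- groups[samples]
  stopifnot(length(groups) == length(samples))
  thr <- vapply(seq_len(ncol(ratios$values)), function(j)
    youden_optimal(roc_curve(ratios$values[, j], groups))$threshold, numeric(1))
  names(thr) <- colnames(ratios$values)
  pairs <- enumerate_ratio_pairs(ratios, min_distinct = min_distinct)
  res <- vapply(seq_len(nrow(pairs)), function(k) {
    r1 <- pairs$ratio_1[k]; r2 <- pairs$ratio_2[k]
    pred <- classify_pair(ratios$values[, r1], ratios$values[, r2],
                          thr[r1], thr[r2], rule = rule)
    ok <- !is.na(pred)
    c(errors = sum(pred[ok] != groups[ok]), n_classified = sum(ok))
  }, numeric(2))
  pairs$errors <- if (nrow(pairs)) as.integer(res["errors", ]) else integer(0)
  pairs$n_classified <- if (nrow(pairs)) as.integer(res["n_classified", ]) else integer(0)
  structure(list(pairs = pairs, thresholds = thr, rule = rule,
                 n_samples = length(samples)),
            class = "pair_error_matrix")
}

#' Perfect double ratios
#'
#' Pairs of ratios that classify every sample correctly, with their fraction
#' of all admissible pairs.
#'
#' @param pem A [pair_error_matrix()] result.
#' @return List: `pairs` (zero-error rows), `n_perfect`, `n_admissible`,
#'   `fraction` (`n_perfect / n_admissible`, in percent when multiplied by
#'   100 by the caller; reported here as a proportion).
#' @export
perfect_pairs <- function(pem) {
  stopifnot(inherits(pem, "pair_error_matrix"))
  perf <- pem$pairs[pem$pairs$errors == 0 &
                      pem$pairs$n_classified == pem$n_samples, , drop = FALSE]
  row.names(perf) <- NULL
  list(pairs = perf, n_perfect = nrow(perf), n_admissible = nrow(pem$pairs),
       fraction = if (nrow(pem$pairs)) nrow(perf) / nrow(pem$pairs) else NA_real_)
}
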