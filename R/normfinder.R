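#' Grouped reference-gene stability values
#'
#' NormFinder-style stability scoring for candidate normalizers in a two-group
#' design. The model decomposes, after centering each sample over the
#' candidate genes, the gene-by-group interaction ("does this gene move with
#' the groups?") and the intragroup variance ("how noisy is it within a
#' group?"), and combines both into a single stability value per gene — lower
#' is more stable.
#'
#' Computation, on the log2 scale:
#' \enumerate{
#'   \item center each sample: `z[i, j] = x[i, j] - mean_i x[i, j]`;
#'   \item per gene i and group g: mean `zbar[i, g]` and residual variance
#'     `v[i, g]` (denominator `k_g - 1`, `k_g` samples in group g);
#'   \item raw interaction `d[i, g] = zbar[i, g] - zbar[i, .] - zbar[., g] + zbar[., .]`;
#'   \item method-of-moments interaction variance
#'     `tau2 = max(0, sum(d^2) / ((n - 1)(G - 1)) - mean(v / k))`, truncated at 0;
#'   \item shrunken deviation `dt[i, g] = d[i, g] * tau2 / (tau2 + v[i, g]/k_g)`;
#'   \item stability `rho_i = mean_g( |dt[i, g]| + sqrt((v[i, g]/k_g) * tau2 / (tau2 + v[i, g]/k_g)) )`.
#' }
#'
#' @param x A [mir_expr] holding the candidate genes (>= 3) over two groups
#'   with >= 2 samples each.
#' @return A list of class `stability_result`: `stability` (data.frame
#'   `mirna_id`, `rho`, `mean_expr`), `d_shrunk` and `intra_var` (gene x group
#'   matrices), `tau2`.
#' @examples
#' x <- simulate_microarray(group_design(5, 5), sim_params(n_mirnas = 30, seed = 4))
#' head(stability_values(x)$stability)
#' @export
stability_values <- function(x) {
  stopifnot(inherits(x, "mir_expr"))
  lv <- levels(x$groups)
  k <- table(x$groups)
  if (any(k < 2)) stop("each group needs >= 2 samples (variance undefined)")
  n <- nrow(x$values)
  if (n < 3) stop("need >= 3 candidate miRNAs")
  G <- length(lv)
  z <- sweep(x$values, 2, colMeans(x$values))
  zbar <- vapply(lv, function(g) rowMeans(z[, x$groups == g, drop = FALSE]),
                 numeric(n))
  v <- vapply(lv, function(g) apply(z[, x$groups == g, drop = FALSE], 1, stats::var),
              numeric(n))
  dimnames(zbar) <- dimnames(v) <- list(rownames(x$values), lv)
  vk <- sweep(v, 2, as.numeric(k[lv]), "/")
  d <- zbar - rowMeans(zbar) -
    matrix(colMeans(zbar), n, G, byrow = TRUE) + mean(zbar)
  tau2 <- max(0, sum(d^2) / ((n - 1) * (G - 1)) - mean(vk))
  denom <- tau2 + vk
  shrink <- ifelse(denom > 0, tau2 / denom, 0)
  dt <- d * shrink
  rho <- rowMeans(abs(dt) + sqrt(vk * shrink))
  structure(list(
    stability = data.frame(mirna_id = rownames(x$values), rho = unname(rho),
                           mean_expr = unname(rowMeans(x$values)),
                           row.names = NULL, stringsAsFactors = FALSE),
    d_shrunk = dt, intra_var = v, tau2 = tau2), class = "stability_result")
}

#' Select the most stable normalizers
#'
#' Filters candidates on mean log2 expression, stability value and (optionally)
#' probe availability, then keeps the `k` genes with the smallest stability
#' value. Ties break toward higher mean expression, then lexicographic id.
#'
#' @param stab A [stability_values()] result.
#' @param x The [mir_expr] the stabilities were computed on (for expression).
#' @param expr_min Minimum mean log2 expression (inclusive, default 5).
#' @param stability_max Stability upper bound (strict `<`, default 0.25).
#' @param k Number of normalizers to retain (default 3).
#' @param probe_list Optional id vector; when given, candidates must be in it.
#' @return A list of class `normalizer_set`: `mirna_ids` (length `k`),
#'   `stability` (their rho values), `factors` (per-sample normalization
#'   factor: arithmetic mean of the normalizers' log2 values = log2 geometric
#'   mean on the linear scale).
#' @export
select_normalizers <- function(stab, x, expr_min = 5, stability_max = 0.25,
                               k = 3, probe_list = NULL) {
  stopifnot(inherits(stab, "stability_result"), inherits(x, "mir_expr"))
  s <- stab$stability
  pass <- s$mean_expr >= expr_min & s$rho < stability_max
  if (!is.null(probe_list)) pass <- pass & s$mirna_id %in% probe_list
  cand <- s[pass, , drop = FALSE]
  if (nrow(cand) < k)
    stop(sprintf("only %d candidate(s) pass the filters; %d required",
                 nrow(cand), k))
  ord <- order(cand$rho, -cand$mean_expr, cand$mirna_id)
  top <- cand[ord[seq_len(k)], , drop = FALSE]
  factors <- colMeans(x$values[top$mirna_id, , drop = FALSE])
  structure(list(mirna_ids = top$mirna_id,
                 stability = setNames(top$rho, top$mirna_id),
                 factors = factors),
            class = "normalizer_set")
}

#' @export
print.normalizer_set <- function(x, ...) {
  cat("<normalizer_set>", paste(x$mirna_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Geometric-mean normalization
#'
#' Subtracts, per sample, the arithmetic mean of the normalizers' log2 values
#' from every miRNA — the log-space equivalent of dividing by the geometric
#' mean of the normalizers on the linear scale. When the normalizers are
#' noise-free this removes per-sample offsets exactly.
#'
#' @param x A [mir_expr].
#' @param normalizers A [select_normalizers()] result, or a character vector
#'   of normalizer miRNA ids present in `x`.
#' @return A [mir_expr] of normalized log2 values.
#' @export
normalize_expr <- function(x, normalizers) {
  stopifnot(inherits(x, "mir_expr"))
  ids <- if (inherits(normalizers, "normalizer_set")) normalizers$mirna_ids
         else normalizers
  bad <- setdiff(ids, rownames(x$values))
  if (length(bad)) stop("normalizer(s) missing from matrix: ",
                        paste(bad, collapse = ", "))
  factors <- colMeans(x$values[ids, , drop = FALSE])
  mir_expr(sweep(x$values, 2, factors), x$groups)
}
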