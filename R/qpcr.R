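#' Aggregate Cq technical replicates
#'
#' Arithmetic mean and SD of the available replicate Cq values per
#' (sample, miRNA). No automatic outlier removal is performed; the SD is
#' reported for QC. A (sample, miRNA) combination with no finite replicate is
#' kept with `cq_mean = NA` (missingness propagates, it is never coerced to a
#' value).
#'
#' @param cq Long-format data.frame with columns `sample_id`, `mirna_id`,
#'   `replicate`, `cq` (Cq in PCR cycles; `NA` = undetermined).
#' @return Data.frame with one row per (sample, miRNA): `cq_mean`, `cq_sd`
#'   (`NA` when fewer than 2 replicates), `n_replicates`.
#' @examples
#' cq <- data.frame(sample_id = "s1", mirna_id = "miR-a",
#'                  replicate = 1:3, cq = c(24.0, 24.2, 24.4))
#' aggregate_replicates(cq)  # mean 24.2, SD 0.2
#' @export
aggregate_replicates <- function(cq) {
  need <- c("sample_id", "mirna_id", "replicate", "cq")
  if (!all(need %in% names(cq)))
    stop("cq table must have columns: ", paste(need, collapse = ", "))
  if (any(cq$cq <= 0, na.rm = TRUE)) stop("Cq values must be > 0")
  key <- interaction(cq$sample_id, cq$mirna_id, drop = TRUE, sep = "\r")
  agg <- function(f) tapply(cq$cq, key, f)
  m <- agg(function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  s <- agg(function(v) if (sum(!is.na(v)) < 2) NA_real_ else stats::sd(v, na.rm = TRUE))
  n <- agg(function(v) sum(!is.na(v)))
  parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
  out <- data.frame(sample_id = parts[, 1], mirna_id = parts[, 2],
                    cq_mean = as.numeric(m), cq_sd = as.numeric(s),
                    n_replicates = as.integer(n),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$sample_id, out$mirna_id), , drop = FALSE]
}

#' Relative expression by the 2^-deltaCq method
#'
#' For each sample the reference Cq is the arithmetic mean of the normalizer
#' miRNAs' (aggregated) Cq values — the geometric mean on the linear scale.
#' Then `deltaCq = Cq_target - Cq_ref` and the relative expression is
#' `2^-deltaCq`. A sample in which any normalizer is missing is excluded for
#' all miRNAs, with a warning.
#'
#' @param agg Aggregated Cq table from [aggregate_replicates()] (a raw long
#'   table is aggregated automatically).
#' @param normalizers Character vector of normalizer miRNA ids, or a
#'   `normalizer_set`.
#' @return A list of class `rel_expr`: `delta_cq` and `rel` (samples x miRNA
#'   matrices of deltaCq and `2^-deltaCq`; normalizer columns included),
#'   `cq_ref` (per-sample reference Cq), `normalizers`.
#' @examples
#' cq <- data.frame(sample_id = "s1", mirna_id = c("t", "n1", "n2", "n3"),
#'                  replicate = 1, cq = c(25, 20, 21, 22))
#' delta_cq(cq, c("n1", "n2", "n3"))$rel[, "t"]  # 2^-4 = 0.0625
#' @export
delta_cq <- function(agg, normalizers) {
  if (inherits(normalizers, "normalizer_set")) normalizers <- normalizers$mirna_ids
  if (!"cq_mean" %in% names(agg)) agg <- aggregate_replicates(agg)
  samples <- sort(unique(agg$sample_id))
  mirnas <- unique(agg$mirna_id)
  bad <- setdiff(normalizers, mirnas)
  if (length(bad)) stop("normalizer(s) not measured: ", paste(bad, collapse = ", "))
  cqm <- matrix(NA_real_, length(samples), length(mirnas),
                dimnames = list(samples, mirnas))
  cqm[cbind(agg$sample_id, agg$mirna_id)] <- agg$cq_mean
  ref <- rowMeans(cqm[, normalizers, drop = FALSE])
  drop <- is.na(ref)
  if (any(drop)) {
    warning("excluding sample(s) with missing normalizer Cq: ",
            paste(samples[drop], collapse = ", "))
    cqm <- cqm[!drop, , drop = FALSE]
    ref <- ref[!drop]
  }
  dcq <- sweep(cqm, 1, ref)
  structure(list(delta_cq = dcq, rel = 2^(-dcq), cq_ref = ref,
                 normalizers = normalizers),
            class = "rel_expr")
}

#' Group fold-change by the 2^-deltadeltaCq method
#'
#' Per miRNA: `ddCq = mean deltaCq(M) - mean deltaCq(B)` and fold-change
#' `2^-ddCq` (M relative to B; > 1 means up-regulated in M).
#'
#' @param rel A [delta_cq()] result.
#' @param groups Named two-level factor (levels `B`, `M`) covering the samples
#'   retained in `rel`.
#' @return Data.frame with `mirna_id`, `delta_delta_cq`, `fold_change`.
#' @export
delta_delta_cq <- function(rel, groups) {
  stopifnot(inherits(rel, "rel_expr"))
  groups <- as.factor(groups)
  samples <- rownames(rel$delta_cq)
  if (is.null(names(groups))) stop("`groups` must be named by sample id")
  miss <- setdiff(samples, names(groups))
  if (length(miss)) stop("no group for sample(s): ", paste(miss, collapse = ", "))
  g <- groups[samples]
  if (!all(c("B", "M") %in% g)) stop("both groups must be present")
  mb <- colMeans(rel$delta_cq[g == "B", , drop = FALSE], na.rm = TRUE)
  mm <- colMeans(rel$delta_cq[g == "M", , drop = FALSE], na.rm = TRUE)
  ddcq <- mm - mb
  data.frame(mirna_id = colnames(rel$delta_cq),
             delta_delta_cq = unname(ddcq),
             fold_change = unname(2^(-ddcq)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Equal-variance two-sample t-test (B vs M)
#'
#' Pooled-variance Student's t with the B-minus-M sign convention, two-sided.
#' By default the test runs on the log2 scale (`-deltaCq`), where the
#' equal-variance assumption is more defensible; pass linear-scale values with
#' `log2_transform = TRUE` to convert, or test linear values directly.
#' Degenerate zero-variance inputs do not error: equal means give `t = 0,
#' p = 1`; unequal means give `p = 0` with a `degenerate` flag.
#'
#' @param values Numeric per-sample measurements (named by sample or aligned
#'   with `groups`).
#' @param groups Two-level factor (levels `B`, `M`).
#' @param log2_transform If `TRUE`, test `log2(values)`.
#' @return List: `t`, `p`, `df`, `degenerate`.
#' @examples
#' differential_test(c(1, 2, 3, 4, 5, 6),
#'                   factor(rep(c("B", "M"), each = 3)))  # t = -3.674
#' @export
differential_test <- function(values, groups, log2_transform = FALSE) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  if (log2_transform) {
    if (any(values <= 0, na.rm = TRUE)) stop("log2 transform needs positive values")
    values <- log2(values)
  }
  ok <- !is.na(values)
  vb <- values[ok & groups == "B"]; vm <- values[ok & groups == "M"]
  if (length(vb) < 2 || length(vm) < 2) stop("need >= 2 samples per group")
  pooled_var <- (sum((vb - mean(vb))^2) + sum((vm - mean(vm))^2)) /
    (length(vb) + length(vm) - 2)
  if (pooled_var == 0) {
    if (mean(vb) == mean(vm)) return(list(t = 0, p = 1,
                                          df = length(vb) + length(vm) - 2,
                                          degenerate = TRUE))
    return(list(t = sign(mean(vb) - mean(vm)) * Inf, p = 0,
                df = length(vb) + length(vm) - 2, degenerate = TRUE))
  }
  tt <- stats::t.test(vb, vm, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}
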