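#' Two-group study design
#'
#' Describes the sample layout of a two-group (borderline vs malignant)
#' comparison. Defaults mirror a small FFPE validation cohort of 11 borderline
#' and 12 malignant tumors.
#'
#' @param n_borderline Number of samples in group B (>= 2).
#' @param n_malignant Number of samples in group M (>= 2).
#' @return A list of class `group_design` with `sample_ids` and a named
#'   `groups` factor with levels `B`, `M`.
#' @examples
#' d <- group_design(3, 3)
#' table(d$groups)
#' @export
group_design <- function(n_borderline = 11, n_malignant = 12) {
  if (n_borderline < 2 || n_malignant < 2)
    stop("each group needs at least 2 samples")
  ids <- c(sprintf("B%02d", seq_len(n_borderline)),
           sprintf("M%02d", seq_len(n_malignant)))
  groups <- factor(rep(c("B", "M"), c(n_borderline, n_malignant)),
                   levels = c("B", "M"))
  names(groups) <- ids
  structure(list(sample_ids = ids, groups = groups,
                 n_borderline = n_borderline, n_malignant = n_malignant),
            class = "group_design")
}

#' Simulation parameters with known ground truth
#'
#' Parameters for the synthetic two-group generator. Baselines are drawn
#' uniformly on a log2-intensity interval typical of RMA-normalized miRNA
#' arrays (planted biomarker and normalizer baselines are kept in the upper
#' part of that interval — validated assay targets are well-expressed, while
#' background miRNAs straddle the detection filter); differential miRNAs
#' receive additive log2 group effects in the malignant group; designated normalizer miRNAs carry no group effect and a
#' reduced noise SD; every sample receives a shared additive offset emulating
#' RNA-amount / labeling variation. The same latent expression feeds both the
#' microarray view and the Cq view (affine map with slope -1), so
#' normalization and ratio cancellation can be demonstrated against one ground
#' truth.
#'
#' Defaults encode the reference study conditions: 5 up-regulated miRNAs at
#' +2 log2, 10 down-regulated at -2 log2, 5 stable normalizer candidates,
#' array noise SD 0.5 log2, sample offsets SD 0.5 log2, Cq intercept 30 and
#' replicate SD 0.2 cycles.
#'
#' @param n_mirnas Total number of miRNAs (background + planted).
#' @param baseline_range Length-2 interval for uniform baseline log2 means.
#' @param noise_sd Per-measurement noise SD, log2 units (> 0).
#' @param de_up Named numeric vector: up-regulated miRNA ids -> log2 effect
#'   (all > 0). Ids not of the generated `mir-####` form are appended.
#' @param de_down Named numeric vector: down-regulated ids -> log2 effect (< 0).
#' @param normalizer_ids Character vector of stable-normalizer ids.
#' @param normalizer_sd Noise SD for normalizer miRNAs (<= `noise_sd`).
#' @param sample_offset_sd SD of the per-sample additive offset, log2 units.
#' @param cq_intercept Intercept of the affine log2-expression -> Cq map
#'   (slope is -1: one PCR cycle per log2 unit, perfect efficiency).
#' @param replicate_sd Cq replicate noise SD, cycles (>= 0).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `sim_params`.
#' @examples
#' p <- sim_params(n_mirnas = 50, seed = 7)
#' names(p$de_up)
#' @export
sim_params <- function(n_mirnas = 500,
                       baseline_range = c(4, 12),
                       noise_sd = 0.5,
                       de_up = setNames(rep(2, 5), paste0("up-", 1:5)),
                       de_down = setNames(rep(-2, 10), paste0("down-", 1:10)),
                       normalizer_ids = paste0("norm-", 1:5),
                       normalizer_sd = 0.1,
                       sample_offset_sd = 0.5,
                       cq_intercept = 30,
                       replicate_sd = 0.2,
                       seed = 1L) {
  stopifnot(length(baseline_range) == 2, baseline_range[1] < baseline_range[2])
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (replicate_sd < 0) stop("replicate_sd must be >= 0")
  if (normalizer_sd > noise_sd) stop("normalizer_sd must be <= noise_sd")
  if (length(de_up) && (is.null(names(de_up)) || any(de_up <= 0)))
    stop("de_up must be a named vector of positive log2 effects")
  if (length(de_down) && (is.null(names(de_down)) || any(de_down >= 0)))
    stop("de_down must be a named vector of negative log2 effects")
  special <- c(names(de_up), names(de_down), normalizer_ids)
  if (anyDuplicated(special))
    stop("de_up, de_down and normalizer_ids must be pairwise disjoint")
  if (length(special) > n_mirnas)
    stop("n_mirnas smaller than the number of planted miRNAs")
  structure(list(n_mirnas = n_mirnas, baseline_range = baseline_range,
                 noise_sd = noise_sd, de_up = de_up, de_down = de_down,
                 normalizer_ids = normalizer_ids, normalizer_sd = normalizer_sd,
                 sample_offset_sd = sample_offset_sd,
                 cq_intercept = cq_intercept, replicate_sd = replicate_sd,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Latent ground truth shared by the microarray and qPCR views: baseline means,
# group effects and per-sample offsets, all deterministic given the seed.
sim_truth <- function(design, params) {
  stopifnot(inherits(design, "group_design"), inherits(params, "sim_params"))
  special <- c(names(params$de_up), names(params$de_down), params$normalizer_ids)
  n_bg <- params$n_mirnas - length(special)
  ids <- c(special, if (n_bg > 0) sprintf("mir-%04d", seq_len(n_bg)))
  set.seed(params$seed)
  mu <- stats::runif(params$n_mirnas, params$baseline_range[1], params$baseline_range[2])
  names(mu) <- ids
  # planted biomarkers and normalizers are well-expressed by construction
  # (validated assay targets sit above the detection filter); background
  # baselines straddle it
  lo_planted <- min(params$baseline_range[1] + 2, params$baseline_range[2])
  mu[special] <- pmax(mu[special], lo_planted)
  offsets <- stats::rnorm(length(design$sample_ids), 0, params$sample_offset_sd)
  names(offsets) <- design$sample_ids
  delta <- setNames(numeric(params$n_mirnas), ids)
  delta[names(params$de_up)] <- params$de_up
  delta[names(params$de_down)] <- params$de_down
  sd_i <- setNames(rep(params$noise_sd, params$n_mirnas), ids)
  sd_i[params$normalizer_ids] <- params$normalizer_sd
  list(ids = ids, mu = mu, delta = delta, sd = sd_i, offsets = offsets)
}

#' Simulate a two-group microarray-like log2 expression matrix
#'
#' Generates `x[i, j] = mu_i + delta_i * 1[group(j) == M] + s_j + eps_ij`
#' with `eps ~ N(0, noise_sd^2)` (reduced SD for normalizer miRNAs) and
#' per-sample offsets `s_j ~ N(0, sample_offset_sd^2)`. Deterministic given
#' `params$seed`; the offsets `s_j` are identical to those used by
#' [simulate_qpcr()] for the same design/params, so the two views describe the
#' same virtual samples.
#'
#' @param design A [group_design].
#' @param params A [sim_params].
#' @return A [mir_expr] with attribute `truth` (list: `mu`, `delta`, `sd`,
#'   `offsets`, plus the planted id sets and the seed).
#' @examples
#' x <- simulate_microarray(group_design(3, 3), sim_params(n_mirnas = 40, seed = 2))
#' dim(x)
#' @export
simulate_microarray <- function(design, params) {
  tr <- sim_truth(design, params)
  n_i <- length(tr$ids); n_j <- length(design$sample_ids)
  is_m <- design$groups == "M"
  # fresh stream, decoupled from the shared truth draw
  set.seed(params$seed + 1L)
  eps <- matrix(stats::rnorm(n_i * n_j), n_i, n_j) * tr$sd
  vals <- outer(tr$mu + 0, rep(1, n_j)) +
    outer(tr$delta, as.numeric(is_m)) +
    matrix(tr$offsets, n_i, n_j, byrow = TRUE) + eps
  dimnames(vals) <- list(tr$ids, design$sample_ids)
  x <- mir_expr(vals, design$groups)
  attr(x, "truth") <- c(tr, list(de_up = params$de_up, de_down = params$de_down,
                                 normalizer_ids = params$normalizer_ids,
                                 seed = params$seed))
  x
}

#' Simulate an RT-qPCR Cq table consistent with the microarray ground truth
#'
#' Cq values follow the affine map `Cq = intercept - log2 expression` (one
#' cycle per log2 unit, perfect PCR efficiency):
#' `Cq[i, j, r] = cq_intercept - (mu_i + delta_i * 1[M] + s_j) + eta`,
#' `eta ~ N(0, replicate_sd^2)`. The sample offsets `s_j` are shared with
#' [simulate_microarray()] under the same seed.
#'
#' @param design A [group_design].
#' @param params A [sim_params].
#' @param mirna_subset miRNA ids to assay (must exist in the ground truth).
#' @param n_replicates Technical replicates per (sample, miRNA); default 3.
#' @return A long-format data.frame of class `cq_table` with columns
#'   `sample_id`, `mirna_id`, `replicate`, `cq`, and attribute `truth`.
#' @examples
#' p <- sim_params(n_mirnas = 40, seed = 3)
#' cq <- simulate_qpcr(group_design(3, 3), p, c("up-1", "norm-1"))
#' head(cq)
#' @export
simulate_qpcr <- function(design, params, mirna_subset, n_replicates = 3) {
  tr <- sim_truth(design, params)
  if (length(mirna_subset) == 0) stop("mirna_subset must be non-empty")
  bad <- setdiff(mirna_subset, tr$ids)
  if (length(bad)) stop("mirna_subset not in ground truth: ", paste(bad, collapse = ", "))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  is_m <- setNames(design$groups == "M", design$sample_ids)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      sample_id = design$sample_ids,
                      mirna_id = mirna_subset,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  true_log2 <- tr$mu[grid$mirna_id] + tr$delta[grid$mirna_id] *
    as.numeric(is_m[grid$sample_id]) + tr$offsets[grid$sample_id]
  set.seed(params$seed + 2L)
  eta <- stats::rnorm(nrow(grid), 0, params$replicate_sd)
  out <- data.frame(sample_id = grid$sample_id, mirna_id = grid$mirna_id,
                    replicate = grid$replicate,
                    cq = params$cq_intercept - true_log2 + eta,
                    stringsAsFactors = FALSE)
  class(out) <- c("cq_table", "data.frame")
  attr(out, "truth") <- c(tr, list(de_up = params$de_up, de_down = params$de_down,
                                   normalizer_ids = params$normalizer_ids,
                                   seed = params$seed))
  out
}
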