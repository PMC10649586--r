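#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the reference
#' workflow: expression threshold 5 log2, fold-change factor 2, stability
#' bound 0.25, three normalizers, alpha 0.05, AND combination rule,
#' minimum four distinct miRNAs per pair.
#'
#' @param expr_min Log2 expression threshold for selection and normalizers.
#' @param min_factor Linear fold-change factor.
#' @param stability_max Stability upper bound for normalizers.
#' @param k_normalizers Number of normalizers.
#' @param alpha Significance level.
#' @param rule Pair combination rule (`"AND"`, `"OR"`, `"SUM"`).
#' @param min_distinct Minimum distinct miRNAs per ratio pair.
#' @param seed Simulation seed (used when no input files are given).
#' @param design A [group_design] for simulation mode.
#' @param params A [sim_params] for simulation mode (its `seed` is overridden
#'   by `seed` when both are given).
#' @param expr_file,groups_file,probe_file Optional input paths; when
#'   `expr_file` is `NULL` the pipeline simulates its input.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr_min = 5, min_factor = 2, stability_max = 0.25,
                            k_normalizers = 3, alpha = 0.05,
                            rule = c("AND", "OR", "SUM"), min_distinct = 4,
                            seed = 1L, design = group_design(),
                            params = sim_params(seed = seed),
                            expr_file = NULL, groups_file = NULL,
                            probe_file = NULL) {
  rule <- match.arg(rule)
  structure(list(expr_min = expr_min, min_factor = min_factor,
                 stability_max = stability_max, k_normalizers = k_normalizers,
                 alpha = alpha, rule = rule, min_distinct = min_distinct,
                 seed = as.integer(seed), design = design, params = params,
                 expr_file = expr_file, groups_file = groups_file,
                 probe_file = probe_file),
            class = "pipeline_config")
}

#' Run the full ratio-signature pipeline
#'
#' Executes candidate selection, normalizer choice, qPCR-style
#' quantification, ratio construction/testing and the double-ratio pair
#' search, end to end. In simulation mode (no `expr_file`) the input matrix
#' and a matched Cq table are generated from the config's design/params, and
#' the planted up/down sets define the validated miRNA panel; in file mode the
#' up/down panel is taken from the selection funnel (stringent + FC-only,
#' probe-filtered when a probe list is given) and quantification reuses the
#' log2 expression matrix as the relative-expression substrate.
#'
#' The report logs each selection filter's before/after counts so the funnel
#' can be audited on any dataset. Identical config + seed gives identical
#' output.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with elements `funnel` (named
#'   counts), `candidates`, `stability`, `normalizers`, `ratio_summary`,
#'   `pair_errors`, `perfect`, `config`.
#' @examples
#' rep <- run_pipeline(pipeline_config(params = sim_params(n_mirnas = 60, seed = 2)))
#' rep$funnel
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  probe_list <- if (!is.null(config$probe_file)) read_probe_list(config$probe_file)
  simulated <- is.null(config$expr_file)
  if (simulated) {
    params <- config$params
    params$seed <- config$seed
    x <- simulate_microarray(config$design, params)
    truth <- attr(x, "truth")
  } else {
    groups <- read_groups_tsv(config$groups_file)
    x <- read_expression_tsv(config$expr_file, groups = groups)
    truth <- NULL
  }

  stringent <- select_stringent(x, expr_min = config$expr_min,
                                min_factor = config$min_factor)
  fc_only <- select_fc_only(x, min_factor = config$min_factor,
                            direction = "up", exclude = stringent)
  candidates <- rbind(stringent, fc_only)
  candidates <- apply_expression_rule(candidates, expr_B_min = config$expr_min)
  if (!is.null(probe_list))
    candidates <- filter_probe_available(candidates, probe_list)

  stab <- stability_values(x)
  normalizers <- select_normalizers(stab, x, expr_min = config$expr_min,
                                    stability_max = config$stability_max,
                                    k = config$k_normalizers,
                                    probe_list = probe_list)
  x_norm <- normalize_expr(x, normalizers)

  if (simulated) {
    up <- names(truth$de_up); down <- names(truth$de_down)
    cq <- simulate_qpcr(config$design, params,
                        mirna_subset = c(up, down, normalizers$mirna_ids))
    rel <- delta_cq(aggregate_replicates(cq), normalizers$mirna_ids)
  } else {
    sel_up <- candidates$mirna_id[candidates$direction == "up"]
    sel_down <- candidates$mirna_id[candidates$direction == "down"]
    if (!is.null(probe_list)) {
      sel_up <- intersect(sel_up, probe_list)
      sel_down <- intersect(sel_down, probe_list)
    }
    up <- sel_up; down <- sel_down
    rel <- list(rel = t(2^x_norm$values[c(up, down), , drop = FALSE]))
    class(rel) <- "rel_expr"
  }
  if (!length(up) || !length(down))
    stop("pipeline stage `ratios`: need at least one up- and one down-regulated miRNA")

  ratios <- build_ratios(rel$rel, up, down)
  groups <- x$groups
  summary <- test_ratios(ratios, groups, alpha = config$alpha)
  pem <- pair_error_matrix(ratios, groups, rule = config$rule,
                           min_distinct = config$min_distinct)
  perfect <- perfect_pairs(pem)

  funnel <- c(n_mirnas = nrow(x$values),
              stringent = nrow(stringent),
              stringent_up = sum(stringent$direction == "up"),
              stringent_down = sum(stringent$direction == "down"),
              fc_only_up = nrow(fc_only),
              candidates = nrow(candidates),
              probe_available = if (!is.null(probe_list))
                sum(candidates$probe_available) else NA_integer_,
              n_up = length(up), n_down = length(down),
              n_ratios = ncol(ratios$values),
              n_significant = sum(summary$significant),
              n_pairs = nrow(pem$pairs),
              n_perfect = perfect$n_perfect)

  structure(list(funnel = funnel, candidates = candidates,
                 stability = stab$stability, normalizers = normalizers,
                 ratio_summary = summary, pair_errors = pem,
                 perfect = perfect, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  f <- x$funnel
  cat(sprintf("  %d miRNAs -> stringent %d (up %d / down %d), +%d FC-only up\n",
              f["n_mirnas"], f["stringent"], f["stringent_up"],
              f["stringent_down"], f["fc_only_up"]))
  cat(sprintf("  normalizers: %s\n", paste(x$normalizers$mirna_ids, collapse = ", ")))
  cat(sprintf("  %d ratios (%d significant at alpha=%g), %d admissible pairs, %d perfect (rule %s)\n",
              f["n_ratios"], f["n_significant"], x$config$alpha,
              f["n_pairs"], f["n_perfect"], x$pair_errors$rule))
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits the intermediate tables (candidates, stability, ratio summary, pair
#' errors) as TSV, plus a JSON report with the funnel counts, normalizers and
#' perfect pairs.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(report$candidates, "candidates.tsv")
  wt(report$stability, "stability.tsv")
  wt(report$ratio_summary, "ratio_summary.tsv")
  wt(report$pair_errors$pairs, "pair_errors.tsv")
  jsonlite::write_json(
    list(funnel = as.list(report$funnel),
         normalizers = report$normalizers$mirna_ids,
         rule = report$pair_errors$rule,
         perfect_pairs = report$perfect$pairs,
         perfect_fraction = report$perfect$fraction,
         seed = report$config$seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
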