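# Shared fixtures and independent brute-force oracles.

# Small deterministic expression matrix with explicit group means.
toy_expr <- function(b_vals, m_vals, ids = NULL) {
  b_vals <- rbind(b_vals); m_vals <- rbind(m_vals)
  if (is.null(ids)) ids <- paste0("miR-", seq_len(nrow(b_vals)))
  m <- cbind(b_vals, m_vals)
  dimnames(m) <- list(ids, c(paste0("b", seq_len(ncol(b_vals))),
                             paste0("m", seq_len(ncol(m_vals)))))
  mir_expr(m, rep(c("B", "M"), c(ncol(b_vals), ncol(m_vals))))
}

# Oracle: minimum threshold-classifier errors by scanning every cut position
# of the sorted values (direct enumeration, independent of threshold_grid).
brute_errors <- function(values, groups, direction = "up") {
  if (direction == "down") values <- -values
  is_m <- groups == "M"
  cuts <- c(-Inf, sort(values), Inf)
  min(vapply(cuts, function(t) sum((values > t) != is_m), numeric(1)))
}

# Oracle: AUC as the fraction of (M, B) pairs ranked correctly, ties = 1/2.
brute_auc <- function(values, groups) {
  vm <- values[groups == "M"]; vb <- values[groups == "B"]
  tot <- 0
  for (m in vm) for (b in vb) tot <- tot + (m > b) + 0.5 * (m == b)
  tot / (length(vm) * length(vb))
}

# Oracle: best Youden J by scanning every candidate cut (values and +/-Inf).
brute_youden <- function(values, groups) {
  is_m <- groups == "M"
  cuts <- c(-Inf, sort(unique(values)), Inf)
  best <- -Inf
  for (t in cuts) {
    sens <- mean(values[is_m] > t)
    spec <- mean(values[!is_m] <= t)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Oracle: admissible ratio pairs by exhaustive set comparison.
brute_pairs <- function(a, b) {
  up <- paste0("u", seq_len(a)); down <- paste0("d", seq_len(b))
  ratios <- expand.grid(u = up, d = down, stringsAsFactors = FALSE)
  n <- 0L
  for (i in seq_len(nrow(ratios) - 1)) for (j in (i + 1):nrow(ratios)) {
    ids <- unique(c(ratios$u[i], ratios$d[i], ratios$u[j], ratios$d[j]))
    if (length(ids) >= 4) n <- n + 1L
  }
  n
}

random_groups <- function(n_b, n_m) factor(rep(c("B", "M"), c(n_b, n_m)))
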