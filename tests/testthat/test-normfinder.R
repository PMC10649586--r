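test_that("constant candidates get stability zero", {
  m <- matrix(rep(c(5, 7, 9), 6), 3, 6,
              dimnames = list(paste0("n", 1:3), paste0("s", 1:6)))
  x <- mir_expr(m, rep(c("B", "M"), each = 3))
  s <- stability_values(x)
  expect_equal(s$stability$rho, rep(0, 3))
  expect_equal(s$tau2, 0)
})

test_that("a gene with an injected group effect has the largest rho", {
  set.seed(21)
  base <- matrix(rnorm(8 * 10, 8, 0.1), 8, 10,
                 dimnames = list(paste0("n", 1:8), paste0("s", 1:10)))
  g <- rep(c("B", "M"), each = 5)
  base["n1", g == "M"] <- base["n1", g == "M"] + 2
  s <- stability_values(mir_expr(base, g))
  expect_equal(s$stability$mirna_id[which.max(s$stability$rho)], "n1")
})

test_that("rho is symmetric in the group labels", {
  x <- simulate_microarray(group_design(4, 5), sim_params(n_mirnas = 25, seed = 8))
  flipped <- mir_expr(x$values, factor(ifelse(x$groups == "B", "M", "B"),
                                       levels = c("B", "M")))
  expect_equal(stability_values(x)$stability$rho,
               stability_values(flipped)$stability$rho)
})

test_that("rho is invariant to adding per-sample constants", {
  x <- simulate_microarray(group_design(4, 4), sim_params(n_mirnas = 25, seed = 13))
  shifted <- mir_expr(sweep(x$values, 2, rnorm(8, 0, 3), "+"), x$groups)
  expect_equal(stability_values(x)$stability$rho,
               stability_values(shifted)$stability$rho, tolerance = 1e-10)
})

test_that("rho grows with the size of an injected group effect", {
  rho_at <- function(delta) {
    set.seed(31)
    m <- matrix(rnorm(6 * 12, 8, 0.2), 6, 12,
                dimnames = list(paste0("n", 1:6), paste0("s", 1:12)))
    g <- rep(c("B", "M"), each = 6)
    m["n1", g == "M"] <- m["n1", g == "M"] + delta
    s <- stability_values(mir_expr(m, g))
    s$stability$rho[s$stability$mirna_id == "n1"]
  }
  rhos <- vapply(c(0, 0.5, 1, 2, 4), rho_at, numeric(1))
  expect_true(all(diff(rhos) > 0))
})

test_that("normalizer selection filters, ranks and errors as documented", {
  x <- simulate_microarray(group_design(6, 6),
                           sim_params(n_mirnas = 40, seed = 17))
  s <- stability_values(x)
  ns <- select_normalizers(s, x, expr_min = -Inf, stability_max = Inf, k = 3)
  ord <- order(s$stability$rho)
  expect_setequal(ns$mirna_ids, s$stability$mirna_id[ord[1:3]])
  expect_error(select_normalizers(s, x, stability_max = 0), "0 candidate")
  probe <- s$stability$mirna_id[ord[4:10]]
  ns2 <- select_normalizers(s, x, expr_min = -Inf, stability_max = Inf, k = 3,
                            probe_list = probe)
  expect_true(all(ns2$mirna_ids %in% probe))
})

test_that("stability_values rejects undersized inputs", {
  x <- toy_expr(rbind(c(5, 6), c(7, 8)), rbind(c(5), c(7)))
  expect_error(stability_values(x), ">= 2 samples")
})

test_that("geometric-mean normalization removes per-sample offsets exactly", {
  d <- group_design(4, 4)
  p <- sim_params(n_mirnas = 25, noise_sd = 1e-12, normalizer_sd = 1e-13,
                  sample_offset_sd = 2, seed = 23)
  x <- simulate_microarray(d, p)
  xn <- normalize_expr(x, p$normalizer_ids)
  tr <- attr(x, "truth")
  # after normalization no sample-offset term remains: group means differ only
  # by the planted effects, sample columns of a null gene are constant
  expect_lt(max(abs(sweep(xn$values["mir-0001", , drop = FALSE], 1,
                          mean(xn$values["mir-0001", ])))), 1e-8)
  fc_before_offsets <- log2_fold_change(xn, "up-1")
  expect_equal(fc_before_offsets, 2, tolerance = 1e-8)
})

test_that("normalization by constant normalizers is a uniform shift", {
  m <- rbind(tgt = c(6, 7, 8, 9), n1 = rep(5, 4), n2 = rep(5, 4), n3 = rep(5, 4))
  colnames(m) <- paste0("s", 1:4)
  x <- mir_expr(m, rep(c("B", "M"), each = 2))
  xn <- normalize_expr(x, c("n1", "n2", "n3"))
  expect_equal(unname(xn$values["tgt", ]), c(1, 2, 3, 4))
  expect_error(normalize_expr(x, "missing-id"), "missing from matrix")
})

test_that("normalization preserves the trend and magnitude of fold-changes", {
  d <- group_design(6, 6)
  p <- sim_params(n_mirnas = 60, sample_offset_sd = 1.5, seed = 29)
  x <- simulate_microarray(d, p)
  xn <- normalize_expr(x, p$normalizer_ids)
  se <- p$noise_sd * sqrt(1 / 6 + 1 / 6)
  for (id in c(names(p$de_up), names(p$de_down))) {
    delta <- unname(attr(x, "truth")$delta[id])
    # normalized FC recovers the planted effect free of the offset term
    expect_lt(abs(log2_fold_change(xn, id) - delta), 3 * se + 3 * p$normalizer_sd)
    expect_equal(sign(log2_fold_change(xn, id)), sign(delta))
  }
})
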