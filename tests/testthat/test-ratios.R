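test_that("ratio construction enumerates all up x down quotients", {
  set.seed(71)
  m <- matrix(2^runif(15 * 8, 1, 6), 8, 15,
              dimnames = list(paste0("s", 1:8),
                              c(paste0("u", 1:5), paste0("d", 1:10))))
  r <- build_ratios(m, paste0("u", 1:5), paste0("d", 1:10))
  expect_equal(ncol(r$values), 50)
  expect_true(all(r$values > 0))
  expect_equal(unname(r$values[, "u2/d3"]), unname(m[, "u2"] / m[, "d3"]))
  one <- build_ratios(m, "u1", "d1")
  expect_equal(unname(one$values[, 1]), unname(m[, "u1"] / m[, "d1"]))
  expect_error(build_ratios(m, c("u1", "x"), "d1"), "unmeasured")
  expect_error(build_ratios(m, "u1", "u1"), "disjoint")
})

test_that("the normalizer reference cancels in every ratio", {
  set.seed(72)
  samples <- paste0("s", 1:6)
  cq <- expand.grid(sample_id = samples,
                    mirna_id = c("u1", "d1", "n1", "n2", "n3"),
                    replicate = 1, stringsAsFactors = FALSE)
  cq$cq <- runif(nrow(cq), 20, 30)
  rel <- delta_cq(cq, c("n1", "n2", "n3"))
  r_norm <- build_ratios(rel, "u1", "d1")
  # same ratios straight from raw Cq: 2^(Cq_down - Cq_up), no reference at all
  raw <- 2^(cq$cq[cq$mirna_id == "d1"] - cq$cq[cq$mirna_id == "u1"])
  expect_equal(unname(r_norm$values[samples, 1]), raw, tolerance = 1e-12)
})

test_that("ROC handles separation, identical groups and fixed orientation", {
  g <- random_groups(3, 3)
  sep <- roc_curve(c(1, 2, 3, 4, 5, 6), g)
  expect_equal(sep$auc, 1)
  opt <- youden_optimal(sep)
  expect_equal(opt$J, 1)
  expect_equal(opt$sensitivity, 1)
  expect_equal(opt$specificity, 1)
  same <- roc_curve(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(same$auc, 0.5)
  # M-low marker: orientation is never auto-flipped
  rev <- roc_curve(c(4, 5, 6, 1, 2, 3), g)
  expect_equal(rev$auc, 0)
  expect_error(roc_curve(1:3, factor(c("B", "B", "B"), levels = c("B", "M"))),
               "both groups")
})

test_that("degenerate constant values give J* = 0 at an infinite threshold", {
  opt <- youden_optimal(roc_curve(rep(3, 6), random_groups(3, 3)))
  expect_equal(opt$J, 0)
  expect_equal(opt$threshold, Inf)   # specificity tie-break prefers calling B
  expect_equal(opt$specificity, 1)
})

test_that("trapezoid AUC equals the pairwise rank statistic (oracle)", {
  set.seed(73)
  for (rep in 1:300) {
    n_b <- sample(2:6, 1); n_m <- sample(2:6, 1)
    v <- round(rnorm(n_b + n_m, 5, 2), 1)
    g <- random_groups(n_b, n_m)
    expect_equal(roc_curve(v, g)$auc, brute_auc(v, g), tolerance = 1e-12)
  }
})

test_that("Youden optimum equals the exhaustive threshold scan (oracle)", {
  set.seed(74)
  for (rep in 1:300) {
    v <- round(rnorm(10, 5, 2), 1)
    g <- random_groups(5, 5)
    expect_equal(youden_optimal(roc_curve(v, g))$J, brute_youden(v, g),
                 tolerance = 1e-12)
  }
})

test_that("AUC respects orientation duality and monotone invariance", {
  set.seed(75)
  for (rep in 1:50) {
    v <- rnorm(12, 5, 2)
    g <- random_groups(6, 6)
    expect_equal(roc_curve(v, g)$auc + roc_curve(-v, g)$auc, 1)
    expect_equal(roc_curve(exp(v), g)$auc, roc_curve(v, g)$auc)
    expect_equal(roc_curve(log(v - min(v) + 1), g)$auc, roc_curve(v, g)$auc)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(76)
  for (rep in 1:25) {
    v <- rnorm(14, 5, 2)
    g <- random_groups(7, 7)
    ref <- suppressMessages(pROC::auc(pROC::roc(g, v, levels = c("B", "M"),
                                                direction = "<")))
    expect_equal(roc_curve(v, g)$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("per-ratio tests count significance on the log2 scale", {
  set.seed(77)
  samples <- paste0("s", 1:12)
  g <- setNames(random_groups(6, 6), samples)
  base <- matrix(2^rnorm(12 * 3, 6, 0.3), 12, 3,
                 dimnames = list(samples, c("u1", "d1", "d2")))
  base[g == "M", "u1"] <- base[g == "M", "u1"] * 4   # planted 2-log2 separation
  r <- build_ratios(base, "u1", c("d1", "d2"))
  res <- test_ratios(r, g)
  expect_equal(nrow(res), 2)
  expect_true(all(res$significant))
  # identical groups: never significant
  flat <- matrix(rep(2^c(1:6, 1:6), 2), 12, 2,
                 dimnames = list(samples, c("u1", "d1")))
  res0 <- test_ratios(build_ratios(flat, "u1", "d1"), g)
  expect_false(res0$significant)
  expect_equal(res0$auc, 0.5)
})
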