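make_ratio_matrix <- function(a, b, n_samples = 6, seed = 1) {
  set.seed(seed)
  ids <- c(paste0("u", seq_len(a)), paste0("d", seq_len(b)))
  m <- matrix(2^runif(n_samples * (a + b), 1, 6), n_samples, a + b,
              dimnames = list(paste0("s", seq_len(n_samples)), ids))
  build_ratios(m, paste0("u", seq_len(a)), paste0("d", seq_len(b)))
}

test_that("admissible pair enumeration matches the closed form and oracle", {
  for (a in 1:6) for (b in 1:6) {
    pairs <- enumerate_ratio_pairs(make_ratio_matrix(a, b))
    expect_equal(nrow(pairs), pair_count(a, b))
    expect_equal(nrow(pairs), brute_pairs(a, b))
  }
  expect_equal(pair_count(5, 10), 900)
})

test_that("edge cases of pair enumeration behave as documented", {
  expect_equal(nrow(enumerate_ratio_pairs(make_ratio_matrix(1, 2))), 0)
  p22 <- enumerate_ratio_pairs(make_ratio_matrix(2, 2))
  expect_equal(nrow(p22), 2)     # the two disjoint diagonals of the 2x2 grid
  expect_true(all(p22$n_distinct == 4))
  expect_warning(none <- enumerate_ratio_pairs(make_ratio_matrix(3, 3),
                                               min_distinct = 5),
                 "at most 4")
  expect_equal(nrow(none), 0)
})

test_that("pair classification rules combine thresholds as stated", {
  v1 <- c(2, 2, 0.5); v2 <- c(2, 0.5, 0.5)
  pred_and <- classify_pair(v1, v2, 1, 1, "AND")
  pred_or <- classify_pair(v1, v2, 1, 1, "OR")
  expect_equal(as.character(pred_and), c("M", "B", "B"))
  expect_equal(as.character(pred_or), c("M", "M", "B"))
  pred_sum <- classify_pair(v1, v2, 1, 1, "SUM")  # log2 excesses 2,0,-2
  expect_equal(as.character(pred_sum), c("M", "B", "B"))
  # a value exactly on the threshold is called B
  expect_equal(as.character(classify_pair(1, 2, 1, 1, "AND")), "B")
})

test_that("error counts match a brute-force per-sample re-derivation", {
  set.seed(81)
  for (rep in 1:20) {
    r <- make_ratio_matrix(2, 3, n_samples = 10, seed = rep)
    g <- setNames(random_groups(5, 5), rownames(r$values))
    pem <- pair_error_matrix(r, g, rule = "AND")
    thr <- pem$thresholds
    for (k in seq_len(nrow(pem$pairs))) {
      v1 <- r$values[, pem$pairs$ratio_1[k]]
      v2 <- r$values[, pem$pairs$ratio_2[k]]
      manual <- sum((v1 > thr[pem$pairs$ratio_1[k]] &
                     v2 > thr[pem$pairs$ratio_2[k]]) != (g == "M"))
      expect_equal(pem$pairs$errors[k], manual)
    }
    expect_true(all(pem$pairs$errors <= 10))
  }
})

test_that("pair errors are symmetric in member order", {
  r <- make_ratio_matrix(3, 3, n_samples = 8, seed = 91)
  g <- setNames(random_groups(4, 4), rownames(r$values))
  pem <- pair_error_matrix(r, g, rule = "AND")
  key_fwd <- paste(pem$pairs$ratio_1, pem$pairs$ratio_2)
  # rebuild with columns permuted so pair members enumerate in swapped order
  r_rev <- r
  r_rev$values <- r$values[, rev(colnames(r$values))]
  r_rev$info <- r$info[rev(seq_len(nrow(r$info))), ]
  pem_rev <- pair_error_matrix(r_rev, g, rule = "AND")
  key_rev <- paste(pem_rev$pairs$ratio_2, pem_rev$pairs$ratio_1)
  expect_setequal(paste(key_fwd, pem$pairs$errors),
                  paste(key_rev, pem_rev$pairs$errors))
})

test_that("AND false positives never exceed either member's false positives", {
  set.seed(92)
  for (rep in 1:20) {
    r <- make_ratio_matrix(2, 2, n_samples = 12, seed = 100 + rep)
    g <- setNames(random_groups(6, 6), rownames(r$values))
    pem <- pair_error_matrix(r, g, rule = "AND")
    thr <- pem$thresholds
    for (k in seq_len(nrow(pem$pairs))) {
      fp <- function(id) sum(r$values[g == "B", id] > thr[id])
      v1 <- r$values[, pem$pairs$ratio_1[k]]; v2 <- r$values[, pem$pairs$ratio_2[k]]
      fp_pair <- sum(v1[g == "B"] > thr[pem$pairs$ratio_1[k]] &
                     v2[g == "B"] > thr[pem$pairs$ratio_2[k]])
      expect_lte(fp_pair, min(fp(pem$pairs$ratio_1[k]), fp(pem$pairs$ratio_2[k])))
    }
  }
})

test_that("two individually perfect ratios make a zero-error pair under AND", {
  samples <- paste0("s", 1:8)
  g <- setNames(random_groups(4, 4), samples)
  m <- cbind(u1 = c(1, 1, 1, 1, 4, 4, 4, 4), d1 = rep(1, 8),
             u2 = c(2, 2, 2, 2, 8, 8, 8, 8), d2 = rep(1, 8))
  rownames(m) <- samples
  r <- build_ratios(m, c("u1", "u2"), c("d1", "d2"))
  pem <- pair_error_matrix(r, g, rule = "AND")
  pp <- perfect_pairs(pem)
  expect_gte(pp$n_perfect, 1)
  expect_equal(pp$fraction, pp$n_perfect / pp$n_admissible)
  expect_true(all(pem$pairs$errors[match(paste(pp$pairs$ratio_1, pp$pairs$ratio_2),
                                         paste(pem$pairs$ratio_1, pem$pairs$ratio_2))] == 0))
})

test_that("planted two-signal data yields a zero-error pair under AND", {
  # Two independent signal axes: u1/d1 and u2/d2 are clean group separators
  # (the per-sample latent factors e1, e2 cancel within each), while the
  # cross ratios u1/d2, u2/d1 are dominated by e1/e2 noise.
  set.seed(93)
  samples <- paste0("s", 1:10)
  g <- setNames(random_groups(5, 5), samples)
  sig <- 2^(ifelse(g == "M", 2, 0))
  e1 <- 2^rnorm(10, 6, 3); e2 <- 2^rnorm(10, 6, 3)
  m <- cbind(u1 = sig * e1, d1 = e1 / sig, u2 = sig * e2, d2 = e2 / sig)
  rownames(m) <- samples
  r <- build_ratios(m, c("u1", "u2"), c("d1", "d2"))
  pem <- pair_error_matrix(r, g, rule = "AND")
  pp <- perfect_pairs(pem)
  expect_gte(pp$n_perfect, 1)
  expect_true(any(pp$pairs$ratio_1 == "u1/d1" & pp$pairs$ratio_2 == "u2/d2"))
})
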