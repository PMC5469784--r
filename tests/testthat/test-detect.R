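pair_em <- function(X1, X2) {
  make_em(cbind(X1, X2), rep(c("g1", "g2"), c(ncol(X1), ncol(X2))))
}

test_that("Welch statistic, df and p match the closed-form oracle and t.test", {
  x1 <- c(1, 2, 3); x2 <- c(4, 5, 6)
  em <- pair_em(rbind(x1), rbind(x2))
  res <- welch_t(em, c("g1", "g2"))
  o <- oracle_welch(x1, x2)
  expect_equal(res$statistic, o$t)
  expect_equal(res$p_value, o$p)
  # independent cross-check against stats::t.test on random unequal data
  set.seed(4)
  for (i in 1:5) {
    a <- rnorm(4, 0, 1); b <- rnorm(6, 0.5, 2)
    em2 <- pair_em(rbind(c(a, rep(NA, 2))), rbind(b))
    r2 <- welch_t(em2, c("g1", "g2"))
    tt <- t.test(a, b)
    expect_equal(r2$statistic, unname(tt$statistic))
    expect_equal(r2$p_value, tt$p.value)
  }
})

test_that("Welch handles degenerate and identical groups", {
  em <- pair_em(rbind(c(1, 2, 3)), rbind(c(1, 2, 3)))
  res <- welch_t(em, c("g1", "g2"))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # zero variance in both groups
  z <- pair_em(rbind(c(5, 5, 5), c(5, 5, 5)), rbind(c(5, 5, 5), c(7, 7, 7)))
  rz <- welch_t(z, c("g1", "g2"))
  expect_equal(rz$p_value, c(1, 0))
  # fewer than 2 observations per group: NA with a reason
  m <- pair_em(rbind(c(1, NA, NA)), rbind(c(2, 3, 4)))
  rm_ <- welch_t(m, c("g1", "g2"))
  expect_true(is.na(rm_$p_value))
  expect_match(rm_$reason, "fewer than 2")
})

test_that("Welch is shift-invariant and sign-flips under group exchange", {
  sim <- small_sim(30, seed = 19)
  a <- welch_t(sim$matrix, c("g1", "g2"))
  shifted <- sim$matrix
  shifted$values <- shifted$values + 5
  b <- welch_t(shifted, c("g1", "g2"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-9)
  flipped <- welch_t(sim$matrix, c("g2", "g1"))
  expect_equal(a$statistic, -flipped$statistic)
  expect_equal(a$p_value, flipped$p_value)
})

test_that("permutation p-values match exhaustive enumeration", {
  # 2v2 toy: all C(4,2)=6 assignments
  em <- pair_em(rbind(c(1, 2)), rbind(c(10, 11)))
  res <- permutation_test(em, c("g1", "g2"))
  expect_equal(res$p_value, oracle_perm_p(c(1, 2), c(10, 11)))
  expect_equal(res$statistic, 1.5 - 10.5)
  # random 3v3 instances, including one with a missing cell
  set.seed(6)
  for (i in 1:5) {
    x1 <- rnorm(3); x2 <- rnorm(3, 1)
    r <- permutation_test(pair_em(rbind(x1), rbind(x2)), c("g1", "g2"))
    expect_equal(r$p_value, oracle_perm_p(x1, x2))
  }
  xm <- c(2.2, 0.5, NA)
  rmiss <- permutation_test(pair_em(rbind(xm), rbind(c(4, 5, 6))),
                            c("g1", "g2"))
  expect_equal(rmiss$p_value, oracle_perm_p(c(2.2, 0.5), c(4, 5, 6)))
  # all-identical values are fully degenerate
  rdeg <- permutation_test(pair_em(rbind(rep(3, 3)), rbind(rep(3, 3))),
                           c("g1", "g2"))
  expect_equal(rdeg$p_value, 1)
})

test_that("permutation p-values respect the enumeration floor", {
  sim <- small_sim(40, seed = 23, frac_de = 0.5, log_fold_change = 5)
  res <- permutation_test(sim$matrix, c("g1", "g2"))
  expect_true(all(res$p_value >= 2 / choose(6, 3)))
  # Monte-Carlo regime: reproducible under seed, observed always counted
  big <- generate_complete(simulation_params(n_proteins = 15,
                                             n_replicates = 6, seed = 2))
  r1 <- permutation_test(big$matrix, c("g1", "g2"), n_permutations = 200,
                         seed = 5)
  r2 <- permutation_test(big$matrix, c("g1", "g2"), n_permutations = 200,
                         seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$p_value >= 1 / 201))
})

test_that("SAM with s0 = 0 reduces to the Welch ratio and ranking", {
  sim <- small_sim(25, seed = 29)
  sam <- sam_test(sim$matrix, c("g1", "g2"), sam_params(s0 = 0))
  welch <- welch_t(sim$matrix, c("g1", "g2"))
  expect_equal(sam$statistic, welch$statistic, tolerance = 1e-9)
  expect_equal(order(-abs(sam$statistic)), order(-abs(welch$statistic)))
  # equal group means give d = 0
  em <- pair_em(rbind(c(1, 2, 3)), rbind(c(3, 1, 2)))
  expect_equal(sam_test(em, c("g1", "g2"),
                        sam_params(s0 = 0.5))$statistic, 0)
})

test_that("pooled SAM permutation p-values match the exhaustive oracle", {
  set.seed(13)
  n <- 20
  X1 <- matrix(rnorm(n * 3, 10), n, 3)
  X2 <- matrix(rnorm(n * 3, 10), n, 3)
  X2[1, ] <- X2[1, ] + 6  # one large-effect protein
  em <- pair_em(X1, X2)
  res <- sam_test(em, c("g1", "g2"), sam_params(s0 = 0.3))
  expect_equal(res$p_value, oracle_sam_pooled(X1, X2, 0.3))
  expect_equal(res$p_value[1], min(res$p_value))
})

test_that("automatic s0 is a percentile of the standard errors", {
  sim <- small_sim(80, seed = 37)
  res <- sam_test(sim$matrix, c("g1", "g2"))
  s0 <- attr(res, "s0")
  w <- welch_t(sim$matrix, c("g1", "g2"))
  se <- abs((rowMeans(sim$matrix$values[, 4:6]) -
               rowMeans(sim$matrix$values[, 1:3])) / w$statistic)
  expect_gte(s0, 0)
  expect_lte(s0, max(se) + 1e-9)
})

test_that("the modified-t family reduces to t-like and fold-change ranking", {
  sim <- small_sim(30, seed = 41)
  X1 <- sim$matrix$values[, 1:3]; X2 <- sim$matrix$values[, 4:6]
  d_t <- mvdep:::rots_d(X1, X2, alpha0 = 0, alpha1 = 1)
  expect_equal(d_t, welch_t(sim$matrix, c("g1", "g2"))$statistic,
               ignore_attr = TRUE)
  d_fc <- mvdep:::rots_d(X1, X2, alpha0 = 2, alpha1 = 0)
  expect_equal(d_fc, (rowMeans(X1) - rowMeans(X2)) / 2, ignore_attr = TRUE)
})

test_that("reproducibility optimization recovers a strong spiked signal", {
  sim <- generate_complete(simulation_params(
    n_proteins = 500, frac_de = 0.1, log_fold_change = 0.9, noise_sd = 0.3,
    seed = 53))
  res <- rots_test(sim$matrix, c("g1", "g2"),
                   rots_params(bootstrap_B = 40, top_list_K = 200), seed = 7)
  truth <- sim$truth$de_labels[res$protein_id]
  top50 <- order(-abs(res$statistic))[1:50]
  expect_gt(mean(truth[top50]), 0.8)
  z <- attr(res, "z_scores")
  expect_gt(max(z[is.finite(z)]), min(z[is.finite(z)]))
  # determinism under the seed
  res2 <- rots_test(sim$matrix, c("g1", "g2"),
                    rots_params(bootstrap_B = 40, top_list_K = 200), seed = 7)
  expect_identical(res$statistic, res2$statistic)
})

test_that("run_all covers every (method, pair) arm and fills q-values", {
  set.seed(61)
  v <- matrix(rnorm(20 * 15, 20), 20, 15)
  em <- make_em(v, rep(c("A", "B", "C", "D", "E"), each = 3))
  res <- run_all(em, group_design(c("A", "B", "C", "D", "E")),
                 methods = "welch")
  expect_equal(unique(res$pair), c("A-B", "B-C", "C-D", "D-E"))
  expect_equal(nrow(res), 4 * 20)
  one <- res[res$pair == "A-B", ]
  expect_equal(one$q_value, bh_qvalues(one$p_value))
  # single pair, one method
  sim <- small_sim(15, seed = 67)
  r1 <- run_all(sim$matrix, group_design(c("g1", "g2")), methods = "perm")
  expect_equal(nrow(r1), 15)
  # row-order invariance (up to reordering)
  shuf <- sim$matrix
  idx <- sample(15)
  shuf$values <- shuf$values[idx, ]
  r2 <- run_all(shuf, group_design(c("g1", "g2")), methods = "perm")
  expect_equal(r2$p_value[match(r1$protein_id, r2$protein_id)], r1$p_value)
})

test_that("require_complete skips proteins with any missing cell", {
  sim <- small_sim(30, seed = 71)
  g <- assign_grades(sim$matrix)
  masked <- inject_missing(sim$matrix, g, missingness_params(0.15, seed = 2))
  res <- welch_t(masked, c("g1", "g2"), mv_policy = "require_complete")
  has_na <- apply(is.na(masked$values), 1, any)
  expect_true(all(is.na(res$p_value[has_na])))
  expect_true(all(!is.na(res$p_value[!has_na])))
})
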