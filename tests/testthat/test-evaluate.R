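test_that("BH q-values execute the step-up rule", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.2), 0.2)
  # sorted q is non-decreasing; random vectors match the hand-rolled oracle
  set.seed(10)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))
    q <- bh_qvalues(p)
    expect_lt(max(abs(q - oracle_bh(p))), 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  # NAs pass through
  q <- bh_qvalues(c(0.01, NA, 0.03))
  expect_true(is.na(q[2]) && !anyNA(q[-2]))
  expect_error(bh_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("confusion metrics follow their definitions", {
  perfect <- confusion_metrics(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(perfect[c("tpr", "fpr", "fdr", "g_score", "f_score")],
               list(tpr = 1, fpr = 0, fdr = 0, g_score = 1, f_score = 1))
  # TP=2 FP=1 TN=6 FN=1
  calls <- c(rep(TRUE, 3), rep(FALSE, 7))
  truth <- c(TRUE, TRUE, FALSE, TRUE, rep(FALSE, 6))
  cm <- confusion_metrics(calls, truth)
  expect_equal(cm$tpr, 2 / 3)
  expect_equal(cm$fpr, 1 / 7)
  expect_equal(cm$fdr, 1 / 3)
  expect_equal(cm$g_score, sqrt(2 / 3 * 6 / 7))
  # zero positive calls: FDR undefined with reason, TPR = 0
  none <- confusion_metrics(rep(FALSE, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_true(is.na(none$fdr))
  expect_match(none$reasons, "zero positive calls")
  expect_equal(none$tpr, 0)
  # swapping calls and truth swaps FN and FP
  a <- confusion_metrics(calls, truth)
  b <- confusion_metrics(truth, calls)
  expect_equal(a$fn, b$fp)
  expect_equal(a$fp, b$fn)
  expect_error(confusion_metrics(TRUE, c(TRUE, FALSE)), "same length")
})

test_that("pAUC matches the threshold-enumeration oracle", {
  # perfectly separating scores use the whole window
  truth <- c(rep(TRUE, 10), rep(FALSE, 40))
  perfect <- roc_pauc(c(50:41, 40:1), truth)
  expect_equal(perfect$pauc, 0.05)
  # 8-point toy with a tie
  sc <- c(0.9, 0.8, 0.8, 0.6, 0.5, 0.4, 0.3, 0.1)
  tr <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  for (fm in c(0.05, 0.3, 1)) {
    expect_equal(roc_pauc(sc, tr, fpr_max = fm)$pauc,
                 oracle_pauc(sc, tr, fm))
  }
  expect_error(roc_pauc(1:3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("full AUC equals the Mann-Whitney statistic on tie-free scores", {
  set.seed(20)
  sc <- rnorm(60)
  tr <- rbinom(60, 1, 0.4) == 1
  auc <- roc_pauc(sc, tr, fpr_max = 1)$pauc
  u <- unname(wilcox.test(sc[tr], sc[!tr])$statistic)
  expect_equal(auc, u / (sum(tr) * sum(!tr)))
})

test_that("uninformative scores approach the diagonal pAUC limit", {
  set.seed(30)
  n <- 20000
  sc <- runif(n)
  tr <- rep(c(TRUE, FALSE), n / 2)
  expect_lt(abs(roc_pauc(sc, tr)$pauc - 0.05^2 / 2), 4e-4)
})

test_that("detection rate and mean rank follow the top-window definition", {
  p <- c(0.001, 0.002, 0.003, seq(0.1, 0.7, 0.1))
  truth <- c(rep(TRUE, 3), rep(FALSE, 7))
  ev <- detection_rate_mean_rank(p, truth, window = 3)
  expect_equal(ev$dr, 1)
  expect_equal(ev$mr, 2)
  # no true positive in window
  ev0 <- detection_rate_mean_rank(rev(p), truth, window = 2)
  expect_equal(ev0$dr, 0)
  expect_true(is.na(ev0$mr))
  # full-window ties: DR = t/window regardless of tie-break
  evt <- detection_rate_mean_rank(rep(0.5, 10), truth, window = 10)
  expect_equal(evt$dr, 0.3)
  # ties inside the window put true positives first
  evtie <- detection_rate_mean_rank(rep(0.5, 10), truth, window = 3)
  expect_equal(evtie$dr, 1)
  expect_equal(evtie$mr, 2)
  # MR is bounded below by (N+1)/2, attained when positives lead
  set.seed(40)
  for (i in 1:20) {
    pv <- runif(15)
    tv <- rbinom(15, 1, 0.4) == 1
    if (!any(tv)) next
    e <- detection_rate_mean_rank(pv, tv, window = 8)
    if (e$n > 0) expect_gte(e$mr, (e$n + 1) / 2)
  }
  expect_error(detection_rate_mean_rank(p, truth, window = 0), "window")
  expect_error(detection_rate_mean_rank(p, rep(FALSE, 10), window = 3),
               "true positives")
})

test_that("imputation fidelity implements r, MAD and MSD", {
  sim <- small_sim(20, seed = 73)
  ident <- imputation_fidelity(sim$matrix, sim$matrix)
  expect_equal(ident$r_overall, 1)
  expect_equal(ident$mad, rep(0, 6))
  expect_equal(ident$msd, rep(0, 6))
  expect_equal(ident$n0, 0L)
  # one protein deviating by 2 in one replicate
  dev <- sim$matrix
  dev$values[4, 2] <- dev$values[4, 2] + 2
  fid <- imputation_fidelity(sim$matrix, dev)
  expect_equal(fid$mad[2], 2)
  expect_equal(fid$msd[2], 2)
  expect_equal(fid$n0, 1L)
  expect_equal(fid$r_overall, min(fid$r_per_replicate))
  # MSD >= MAD for any deviation pattern (power-mean inequality)
  set.seed(50)
  for (i in 1:10) {
    noisy <- sim$matrix
    noisy$values <- noisy$values + rnorm(length(noisy$values), 0, 0.2)
    f <- imputation_fidelity(sim$matrix, noisy)
    expect_true(all(f$msd >= f$mad - 1e-12))
  }
  expect_error(imputation_fidelity(sim$matrix,
                                   sim$matrix$values[, 1:3]), "congruent")
  flat <- sim$matrix
  flat$values[, 1] <- 1
  expect_error(imputation_fidelity(sim$matrix, flat), "zero variance")
})

test_that("pairwise summaries average per-pair confusion metrics", {
  truth <- setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE), paste0("P", 1:5))
  mk <- function(pair, q) data.frame(pair = pair, protein_id = paste0("P", 1:5),
                                     q_value = q)
  # identical results across 4 pairs equal the single-pair value
  q <- c(0.01, 0.2, 0.03, 0.8, 0.9)
  res4 <- do.call(rbind, lapply(c("A-B", "B-C", "C-D", "D-E"), mk, q = q))
  s4 <- pairwise_summary(res4, truth)
  s1 <- pairwise_summary(mk("A-B", q), truth)
  expect_equal(s4$tpr, s1$tpr)
  expect_equal(s4$fdr, s1$fdr)
  # two pairs with TPR 0.5 and 1 average to 0.75
  res2 <- rbind(mk("A-B", c(0.01, 0.2, 0.5, 0.8, 0.9)),
                mk("B-C", c(0.01, 0.02, 0.5, 0.8, 0.9)))
  expect_equal(pairwise_summary(res2, truth)$tpr, 0.75)
  # a pair with zero calls is excluded from the FDR mean and counted
  res3 <- rbind(mk("A-B", c(0.01, 0.2, 0.5, 0.8, 0.9)),
                mk("B-C", rep(0.9, 5)))
  s3 <- pairwise_summary(res3, truth)
  expect_equal(s3$n_fdr_excluded, 1)
  expect_equal(s3$fdr, 0)
})
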