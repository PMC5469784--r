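#' @name detect
#' @title Differential-expression statistics
#'
#' @description Four per-protein two-group statistics: Welch's t-test
#' ([welch_t()]), a label-permutation test ([permutation_test()]), the SAM
#' d-statistic with a variance-stabilizing fudge factor ([sam_test()]), and a
#' reproducibility-optimized modified-t family ([rots_test()]). All return a
#' `TestResult` data frame with one row per protein: `protein_id`,
#' `statistic`, `p_value`, `q_value` (`NA` until filled by [bh_qvalues()] /
#' [run_all()]), `n1`, `n2` (observations used per group) and `reason`
#' (why a protein could not be tested, else `NA`).
NULL

# ---- shared machinery -----------------------------------------------------

# Row variances with NA removal; NA when fewer than 2 observations.
row_vars <- function(x, means = rowMeans(x, na.rm = TRUE)) {
  n <- rowSums(!is.na(x))
  v <- rowSums((x - means)^2, na.rm = TRUE) / (n - 1)
  v[n < 2] <- NA_real_
  v
}

# Extract the two groups' value matrices for one pair.
pair_values <- function(em, pair) {
  stopifnot(is_expression_matrix(em), length(pair) == 2)
  list(X1 = em$values[, group_columns(em, pair[1]), drop = FALSE],
       X2 = em$values[, group_columns(em, pair[2]), drop = FALSE])
}

new_test_result <- function(ids, statistic, p_value, n1, n2, reason) {
  data.frame(protein_id = ids, statistic = statistic, p_value = p_value,
             q_value = NA_real_, n1 = n1, n2 = n2, reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Both groups' sums are always accumulated from their own columns (never as
# total minus the other group) so that an assignment and its complement give
# bit-exact opposite statistics: the label-exchange tie structure of the
# permutation null is exact in floating point.
perm_pvalue <- function(stats) mean(abs(stats) >= abs(stats[1]))

# Column-index splits of n items into a first group of size k: exhaustive
# enumeration when C(n, k) <= n_max (first column is the observed 1:k
# arrangement), otherwise n_max random splits with the observed arrangement
# prepended, so the observed labelling is always in numerator and
# denominator of the permutation p-value.
enumerate_splits <- function(n, k, n_max) {
  if (choose(n, k) <= n_max) {
    list(mat = utils::combn(n, k), exhaustive = TRUE)
  } else {
    mat <- cbind(seq_len(k),
                 replicate(n_max, sample.int(n, k)))
    list(mat = mat, exhaustive = FALSE)
  }
}

# Two-sample statistic for every split (columns of `mat`) of the value
# vector `pool` (no NAs) into groups of size k and length(pool)-k.
# stat: "meandiff", "t" (Welch), or "d" (SAM with fudge s0).
split_stats_vector <- function(pool, mat, stat, s0 = 0) {
  k <- nrow(mat); n <- length(pool); nb <- n - k
  cmat <- apply(mat, 2, function(idx) seq_len(n)[-idx])
  s1 <- colSums(matrix(pool[mat], nrow = k))
  s2 <- colSums(matrix(pool[cmat], nrow = nb))
  num <- s1 / k - s2 / nb
  if (stat == "meandiff") return(num)
  sq1 <- colSums(matrix(pool[mat]^2, nrow = k))
  sq2 <- colSums(matrix(pool[cmat]^2, nrow = nb))
  v1 <- (sq1 - s1^2 / k) / (k - 1)
  v2 <- (sq2 - s2^2 / nb) / (nb - 1)
  se <- sqrt(pmax(v1, 0) / k + pmax(v2, 0) / nb)
  den <- if (stat == "d") se + s0 else se
  out <- num / den
  out[num == 0 & den == 0] <- 0
  out
}

# Same statistics, vectorized across proteins for complete rows:
# V is proteins x n, `mat` as above. Returns proteins x ncol(mat).
split_stats_matrix <- function(V, mat, stat, s0 = 0) {
  k <- nrow(mat); n <- ncol(V); nb <- n - k
  out <- matrix(NA_real_, nrow(V), ncol(mat))
  if (stat != "meandiff") V2 <- V^2
  for (a in seq_len(ncol(mat))) {
    idx <- mat[, a]
    s1 <- rowSums(V[, idx, drop = FALSE])
    s2 <- rowSums(V[, -idx, drop = FALSE])
    num <- s1 / k - s2 / nb
    if (stat == "meandiff") {
      out[, a] <- num
    } else {
      sq1 <- rowSums(V2[, idx, drop = FALSE])
      sq2 <- rowSums(V2[, -idx, drop = FALSE])
      v1 <- (sq1 - s1^2 / k) / (k - 1)
      v2 <- (sq2 - s2^2 / nb) / (nb - 1)
      se <- sqrt(pmax(v1, 0) / k + pmax(v2, 0) / nb)
      den <- if (stat == "d") se + s0 else se
      o <- num / den
      o[num == 0 & den == 0] <- 0
      out[, a] <- o
    }
  }
  out
}

# Permutation statistics for every protein of a pair: a list with, per
# protein, the vector of split statistics (first element = observed) or NULL
# when the protein is untestable. Complete rows share one vectorized path.
protein_split_stats <- function(X1, X2, stat, s0, n_permutations) {
  n1 <- ncol(X1); n2 <- ncol(X2)
  V <- cbind(X1, X2)
  n_obs1 <- rowSums(!is.na(X1)); n_obs2 <- rowSums(!is.na(X2))
  testable <- n_obs1 >= 2 & n_obs2 >= 2
  out <- vector("list", nrow(V))
  complete <- testable & !apply(is.na(V), 1, any)
  if (any(complete)) {
    sp <- enumerate_splits(n1 + n2, n1, n_permutations)
    stats <- split_stats_matrix(V[complete, , drop = FALSE], sp$mat, stat, s0)
    for (ii in seq_len(sum(complete)))
      out[[which(complete)[ii]]] <- stats[ii, ]
  }
  for (i in which(testable & !complete)) {
    vi <- V[i, ]
    pool <- c(vi[seq_len(n1)][!is.na(vi[seq_len(n1)])],
              vi[n1 + seq_len(n2)][!is.na(vi[n1 + seq_len(n2)])])
    sp <- enumerate_splits(length(pool), n_obs1[i], n_permutations)
    out[[i]] <- split_stats_vector(pool, sp$mat, stat, s0)
  }
  list(stats = out, n_obs1 = n_obs1, n_obs2 = n_obs2, testable = testable)
}

untestable_reason <- function(testable)
  ifelse(testable, NA_character_, "fewer than 2 observed values in a group")

# Apply mv_policy: under "require_complete", proteins with any missing cell
# in the pair's columns are marked untestable.
apply_mv_policy <- function(X1, X2, mv_policy) {
  if (mv_policy == "require_complete") {
    bad <- apply(is.na(cbind(X1, X2)), 1, any)
    X1[bad, ] <- NA_real_
    X2[bad, ] <- NA_real_
  }
  list(X1 = X1, X2 = X2)
}

# ---- Welch ----------------------------------------------------------------

#' Welch's t-test per protein
#'
#' The statistic is `t(i) = (x1bar - x2bar) / s(i)` with the pooled standard
#' error `s(i) = sqrt(s1^2/n1 + s2^2/n2)` (equal group sizes reduce this to
#' `sqrt((s1^2 + s2^2)/n)`), and a two-sided p-value from the t distribution
#' on Welch–Satterthwaite degrees of freedom
#' `(s1^2/n1 + s2^2/n2)^2 / ((s1^2/n1)^2/(n1-1) + (s2^2/n2)^2/(n2-1))`.
#'
#' @param em A log-scale `ExpressionMatrix`.
#' @param pair Length-2 character vector of group labels.
#' @param mv_policy `"ignore"` (default: use available observations, skip
#'   proteins with fewer than 2 per group) or `"require_complete"`.
#' @param df_method `"satterthwaite"` (default) or `"printed"`, a published
#'   variant `df = ((n-1)/n) (s1^2 + s2^2)` retained only for fidelity
#'   experiments; it is not a valid degrees-of-freedom formula.
#' @return A `TestResult` data frame (see [detect]).
#' @export
welch_t <- function(em, pair, mv_policy = c("ignore", "require_complete"),
                    df_method = c("satterthwaite", "printed")) {
  mv_policy <- match.arg(mv_policy)
  df_method <- match.arg(df_method)
  pv <- pair_values(em, pair)
  pv <- apply_mv_policy(pv$X1, pv$X2, mv_policy)
  X1 <- pv$X1; X2 <- pv$X2
  n1 <- rowSums(!is.na(X1)); n2 <- rowSums(!is.na(X2))
  testable <- n1 >= 2 & n2 >= 2
  m1 <- rowMeans(X1, na.rm = TRUE); m2 <- rowMeans(X2, na.rm = TRUE)
  v1 <- row_vars(X1, m1); v2 <- row_vars(X2, m2)
  se <- sqrt(v1 / n1 + v2 / n2)
  num <- m1 - m2
  t <- num / se
  t[num == 0 & se == 0] <- 0  # zero variance, equal means
  df <- if (df_method == "satterthwaite") {
    (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    (n1 - 1) / n1 * (v1 + v2)
  }
  p <- 2 * stats::pt(-abs(t), df)
  p[is.infinite(t)] <- 0   # zero variance, unequal means
  p[t == 0 & se == 0] <- 1
  t[!testable] <- NA_real_; p[!testable] <- NA_real_
  new_test_result(rownames(em$values), t, p, n1, n2,
                  untestable_reason(testable))
}

# ---- permutation test -----------------------------------------------------

#' Two-sample permutation test per protein
#'
#' The statistic is the difference of group means (or the Welch t statistic
#' with `statistic = "t"`); the p-value is the proportion of group-label
#' assignments whose absolute statistic is at least the observed one, the
#' observed arrangement counting in numerator and denominator. All
#' `C(n1+n2, n1)` distinct assignments are enumerated when that number does
#' not exceed `n_permutations`; otherwise `n_permutations` random assignments
#' are drawn.
#'
#' @inheritParams welch_t
#' @param n_permutations Enumeration cap / Monte-Carlo sample size.
#' @param seed RNG seed (used only in the Monte-Carlo regime).
#' @param statistic `"meandiff"` (default) or `"t"`.
#' @return A `TestResult` data frame. p-values are always at least
#'   1 / (number of assignments considered).
#' @export
permutation_test <- function(em, pair, n_permutations = 10000, seed = 1L,
                             statistic = c("meandiff", "t"),
                             mv_policy = c("ignore", "require_complete")) {
  statistic <- match.arg(statistic)
  mv_policy <- match.arg(mv_policy)
  pv <- pair_values(em, pair)
  pv <- apply_mv_policy(pv$X1, pv$X2, mv_policy)
  with_seed(seed, {
    ps <- protein_split_stats(pv$X1, pv$X2, statistic, 0, n_permutations)
    stat <- p <- rep(NA_real_, nrow(pv$X1))
    for (i in which(ps$testable)) {
      s <- ps$stats[[i]]
      stat[i] <- s[1]
      p[i] <- perm_pvalue(s)
    }
    new_test_result(rownames(em$values), stat, p, ps$n_obs1, ps$n_obs2,
                    untestable_reason(ps$testable))
  })
}

# ---- SAM ------------------------------------------------------------------

#' Parameters for the SAM d-statistic
#'
#' @param s0_percentile Percentile (0--100) of the per-protein standard-error
#'   distribution used for the fudge factor `s0`, or `NULL` (default) to
#'   select it automatically by flattening the dispersion of `d(i)` across
#'   the standard-error range (see [sam_test()]).
#' @param s0 Fixed non-negative fudge factor; overrides `s0_percentile`
#'   (`s0 = 0` reduces `d(i)` to the plain ratio of [welch_t()]).
#' @param n_permutations Enumeration cap / Monte-Carlo size for the pooled
#'   permutation null.
#' @return A `SamParams` list.
#' @export
sam_params <- function(s0_percentile = NULL, s0 = NULL,
                       n_permutations = 1000) {
  if (!is.null(s0_percentile))
    stopifnot(s0_percentile >= 0, s0_percentile <= 100)
  if (!is.null(s0)) stopifnot(s0 >= 0)
  structure(list(s0_percentile = s0_percentile, s0 = s0,
                 n_permutations = n_permutations),
            class = "SamParams")
}

# Select s0 on the CV-flattening criterion: over a grid of percentiles of
# {s(i)}, choose the s0 whose d(i) = num/(s + s0) has the most uniform
# spread across the s(i) range, measured as the coefficient of variation of
# the median absolute deviation of d within s-quantile bins.
select_s0 <- function(num, se, percentiles = seq(0, 100, by = 5)) {
  ok <- is.finite(num) & is.finite(se)
  num <- num[ok]; se <- se[ok]
  if (!length(se)) stop("no testable proteins for s0 selection")
  cand <- stats::quantile(se, percentiles / 100, names = FALSE)
  n_bins <- max(2L, min(10L, floor(length(se) / 5)))
  breaks <- unique(stats::quantile(se, seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(se, breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- num / (se + s0)
    mads <- tapply(d, bin, stats::mad)
    mads <- mads[is.finite(mads)]
    if (length(mads) < 2 || mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  if (all(is.infinite(cv))) return(stats::median(se))
  cand[which.min(cv)]
}

#' SAM d-statistic with pooled permutation p-values
#'
#' The statistic is `d(i) = (x1bar - x2bar) / (s(i) + s0)` with `s(i)` the
#' pooled standard error of [welch_t()] and `s0` a small positive fudge
#' factor (a percentile of the `s(i)` distribution) that stabilizes the
#' coefficient of variation of `d(i)` across the abundance-variance range.
#' p-values come from a permutation null of `d` pooled across all proteins:
#' every group-label assignment of every protein contributes its `|d|` to one
#' null distribution (computed with the same `s0`), and
#' `p(i) = P(|d_null| >= |d(i)|)`.
#'
#' @inheritParams welch_t
#' @param params A [sam_params()] object.
#' @param seed RNG seed (Monte-Carlo regime only).
#' @return A `TestResult` data frame with attribute `s0`.
#' @export
sam_test <- function(em, pair, params = sam_params(), seed = 1L,
                     mv_policy = c("ignore", "require_complete")) {
  stopifnot(inherits(params, "SamParams"))
  mv_policy <- match.arg(mv_policy)
  pv <- pair_values(em, pair)
  pv <- apply_mv_policy(pv$X1, pv$X2, mv_policy)
  X1 <- pv$X1; X2 <- pv$X2
  n1 <- rowSums(!is.na(X1)); n2 <- rowSums(!is.na(X2))
  m1 <- rowMeans(X1, na.rm = TRUE); m2 <- rowMeans(X2, na.rm = TRUE)
  se <- sqrt(row_vars(X1, m1) / n1 + row_vars(X2, m2) / n2)
  num <- m1 - m2
  testable <- n1 >= 2 & n2 >= 2
  if (!any(testable)) stop("no testable proteins")
  s0 <- if (!is.null(params$s0)) {
    params$s0
  } else if (is.null(params$s0_percentile)) {
    select_s0(num[testable], se[testable])
  } else {
    stats::quantile(se[testable], params$s0_percentile / 100, names = FALSE)
  }
  with_seed(seed, {
    ps <- protein_split_stats(X1, X2, "d", s0, params$n_permutations)
    d <- rep(NA_real_, nrow(X1))
    d[testable] <- vapply(ps$stats[testable], `[`, numeric(1), 1)
    pool <- abs(unlist(ps$stats[testable], use.names = FALSE))
    p <- rep(NA_real_, nrow(X1))
    p[testable] <- vapply(abs(d[testable]),
                          function(di) mean(pool >= di), numeric(1))
    res <- new_test_result(rownames(em$values), d, p, n1, n2,
                           untestable_reason(testable))
    attr(res, "s0") <- s0
    res
  })
}

# ---- ROTS -----------------------------------------------------------------

#' Parameters for the reproducibility-optimized test statistic
#'
#' @param bootstrap_B Bootstrap/permutation resampling count (default 500).
#' @param top_list_K Maximum top-list length over which reproducibility is
#'   measured (default 1000).
#' @param alpha0_grid Candidate `alpha0` values for the modified-t family
#'   `d = (x1bar - x2bar) / (alpha1 s(i) + alpha0)`; `alpha1 = 1` is paired
#'   with every grid value and `alpha1 = 0` (pure fold-change ranking) is
#'   added as one extra candidate.
#' @param n_permutations Enumeration cap for the pooled permutation p-values
#'   of the selected statistic.
#' @return A `RotsParams` list.
#' @export
rots_params <- function(bootstrap_B = 500, top_list_K = 1000,
                        alpha0_grid = c(0, 0.01, 0.025, 0.05, 0.1, 0.15,
                                        0.25, 0.35, 0.5, 0.75, 1, 1.5, 2, 3),
                        n_permutations = 1000) {
  stopifnot(bootstrap_B >= 2, top_list_K >= 1, all(alpha0_grid >= 0))
  structure(list(bootstrap_B = as.integer(bootstrap_B),
                 top_list_K = as.integer(top_list_K),
                 alpha0_grid = alpha0_grid,
                 n_permutations = n_permutations),
            class = "RotsParams")
}

# Modified-t statistic family on two value matrices.
rots_d <- function(X1, X2, alpha0, alpha1) {
  n1 <- rowSums(!is.na(X1)); n2 <- rowSums(!is.na(X2))
  m1 <- rowMeans(X1, na.rm = TRUE); m2 <- rowMeans(X2, na.rm = TRUE)
  se <- sqrt(row_vars(X1, m1) / n1 + row_vars(X2, m2) / n2)
  num <- m1 - m2
  den <- alpha1 * se + alpha0
  d <- num / den
  d[num == 0 & den == 0] <- 0
  d[n1 < 2 | n2 < 2] <- NA_real_
  d
}

# Rank positions by decreasing |d| (ties and NAs last, stable).
rots_positions <- function(d) {
  pos <- integer(length(d))
  pos[order(-abs(d), seq_along(d), na.last = TRUE)] <- seq_along(d)
  pos
}

#' Reproducibility-optimized test statistic
#'
#' Selects the member of the modified-t family
#' `d_alpha(i) = (x1bar - x2bar) / (alpha1 s(i) + alpha0)` that maximizes the
#' reproducibility of its top-list rankings under bootstrap resampling of
#' replicates within groups. For every candidate `(alpha0, alpha1)` and every
#' top-list length `k`, the average overlap proportion of the two rankings of
#' a bootstrap pair is compared with the same quantity on group-label
#' permuted (null) data, standardized by the bootstrap SD of the observed
#' overlap; the `(alpha0, alpha1, k)` with the largest Z-score wins. The
#' final statistic is `d_alpha*` on the original data with pooled permutation
#' p-values as in [sam_test()].
#'
#' @inheritParams welch_t
#' @param params A [rots_params()] object.
#' @param seed RNG seed.
#' @return A `TestResult` data frame with attributes `alpha0`, `alpha1`,
#'   `top_k`, `z_scores` (per-candidate maxima).
#' @export
rots_test <- function(em, pair, params = rots_params(), seed = 1L,
                      mv_policy = c("ignore", "require_complete")) {
  stopifnot(inherits(params, "RotsParams"))
  mv_policy <- match.arg(mv_policy)
  pv <- pair_values(em, pair)
  pv <- apply_mv_policy(pv$X1, pv$X2, mv_policy)
  X1 <- pv$X1; X2 <- pv$X2
  n1 <- ncol(X1); n2 <- ncol(X2)
  n_prot <- nrow(X1)
  cand <- rbind(data.frame(alpha0 = params$alpha0_grid, alpha1 = 1),
                data.frame(alpha0 = 1, alpha1 = 0))
  k_max <- min(params$top_list_K, n_prot)
  k_grid <- unique(round(exp(seq(log(min(5, k_max)), log(k_max),
                                 length.out = 15))))
  B <- params$bootstrap_B
  with_seed(seed, {
    V <- cbind(X1, X2)
    overlap_obs <- overlap_null <- array(
      NA_real_, c(nrow(cand), length(k_grid), B))
    for (b in seq_len(B)) {
      # observed bootstrap pair: resample replicates within groups
      boots <- lapply(1:2, function(h)
        list(X1[, sample.int(n1, n1, replace = TRUE), drop = FALSE],
             X2[, sample.int(n2, n2, replace = TRUE), drop = FALSE]))
      # null pair: permute group labels, then bootstrap the pseudo-groups
      perm <- sample.int(n1 + n2)
      P1 <- V[, perm[seq_len(n1)], drop = FALSE]
      P2 <- V[, perm[n1 + seq_len(n2)], drop = FALSE]
      nulls <- lapply(1:2, function(h)
        list(P1[, sample.int(n1, n1, replace = TRUE), drop = FALSE],
             P2[, sample.int(n2, n2, replace = TRUE), drop = FALSE]))
      for (ci in seq_len(nrow(cand))) {
        a0 <- cand$alpha0[ci]; a1 <- cand$alpha1[ci]
        po <- lapply(boots, function(bb)
          rots_positions(rots_d(bb[[1]], bb[[2]], a0, a1)))
        pn <- lapply(nulls, function(bb)
          rots_positions(rots_d(bb[[1]], bb[[2]], a0, a1)))
        for (ki in seq_along(k_grid)) {
          k <- k_grid[ki]
          overlap_obs[ci, ki, b] <- sum(po[[1]] <= k & po[[2]] <= k) / k
          overlap_null[ci, ki, b] <- sum(pn[[1]] <= k & pn[[2]] <= k) / k
        }
      }
    }
    mo <- apply(overlap_obs, c(1, 2), mean)
    mn <- apply(overlap_null, c(1, 2), mean)
    so <- apply(overlap_obs, c(1, 2), stats::sd)
    z <- (mo - mn) / so
    z[so == 0] <- -Inf
    if (all(!is.finite(z)))
      stop("reproducibility undefined: all candidate Z-scores degenerate")
    best <- which(z == max(z, na.rm = TRUE), arr.ind = TRUE)[1, ]
    a0 <- cand$alpha0[best[1]]
    a1 <- cand$alpha1[best[1]]
    # pooled permutation p-values for the selected statistic
    ps <- protein_split_stats_rots(X1, X2, a0, a1, params$n_permutations)
    d <- rep(NA_real_, n_prot)
    d[ps$testable] <- vapply(ps$stats[ps$testable], `[`, numeric(1), 1)
    pool <- abs(unlist(ps$stats[ps$testable], use.names = FALSE))
    p <- rep(NA_real_, n_prot)
    p[ps$testable] <- vapply(abs(d[ps$testable]),
                             function(di) mean(pool >= di), numeric(1))
    res <- new_test_result(rownames(em$values), d, p, ps$n_obs1, ps$n_obs2,
                           untestable_reason(ps$testable))
    attr(res, "alpha0") <- a0
    attr(res, "alpha1") <- a1
    attr(res, "top_k") <- k_grid[best[2]]
    attr(res, "z_scores") <- apply(z, 1, max)
    res
  })
}

# Split statistics for the selected ROTS statistic: alpha1 = 1 gives the SAM
# machinery with s0 = alpha0; alpha1 = 0 is a scaled mean difference.
protein_split_stats_rots <- function(X1, X2, alpha0, alpha1, n_permutations) {
  if (alpha1 == 1) {
    protein_split_stats(X1, X2, "d", alpha0, n_permutations)
  } else {
    ps <- protein_split_stats(X1, X2, "meandiff", 0, n_permutations)
    ps$stats <- lapply(ps$stats, function(s) if (is.null(s)) s else s / alpha0)
    ps
  }
}

# ---- batch runner ---------------------------------------------------------

#' Run several detection methods over the pairs of a design
#'
#' Applies each requested method to each pair of the design, fills in
#' Benjamini–Hochberg q-values per (method, pair), and binds everything into
#' one long data frame. Per-(method, pair) RNG seeds are derived from `seed`
#' so arms are independent and extensible. A protein that cannot be tested
#' yields an `NA` row with a reason instead of aborting the batch.
#'
#' @param em A log-scale `ExpressionMatrix`.
#' @param design A [group_design()].
#' @param methods Subset of `c("welch", "perm", "sam", "rots")`.
#' @param mv_policy Passed to every method.
#' @param seed Master seed.
#' @param perm_n,sam_par,rots_par Method options.
#' @return A data frame with columns `method`, `pair`, and the `TestResult`
#'   columns.
#' @export
run_all <- function(em, design, methods = c("welch", "perm", "sam", "rots"),
                    mv_policy = c("ignore", "require_complete"), seed = 1L,
                    perm_n = 10000, sam_par = sam_params(),
                    rots_par = rots_params()) {
  stopifnot(inherits(design, "GroupDesign"))
  mv_policy <- match.arg(mv_policy)
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  for (pair in design$pairs) {
    pname <- paste(pair, collapse = "-")
    for (meth in methods) {
      s <- string_seed("detect", seed, meth, pname)
      res <- switch(meth,
        welch = welch_t(em, pair, mv_policy),
        perm  = permutation_test(em, pair, perm_n, seed = s,
                                 mv_policy = mv_policy),
        sam   = sam_test(em, pair, sam_par, seed = s, mv_policy = mv_policy),
        rots  = rots_test(em, pair, rots_par, seed = s,
                          mv_policy = mv_policy))
      res$q_value <- bh_qvalues(res$p_value)
      out[[paste(meth, pname)]] <-
        cbind(method = meth, pair = pname, res)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
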