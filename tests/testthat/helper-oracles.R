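# Fixtures built in code and independent brute-force oracles. Oracles are
# deliberately naive (full enumeration, explicit formulas) and share no code
# with the implementation they check.

make_em <- function(values, groups, scale = "log", ids = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  expression_matrix(values, groups = groups, scale = scale,
                    protein_ids = ids)
}

small_sim <- function(n = 50, seed = 1, ...) {
  generate_complete(simulation_params(n_proteins = n, seed = seed, ...))
}

# BH step-up executed literally on the sorted p-values.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Welch's t from the textbook formulas, value by value.
oracle_welch <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  se2 <- var(x1) / n1 + var(x2) / n2
  t <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((var(x1) / n1)^2 / (n1 - 1) + (var(x2) / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exhaustive two-sided mean-difference permutation p, enumerating every
# C(n1+n2, n1) assignment of the pooled values.
oracle_perm_p <- function(x1, x2) {
  pool <- c(x1, x2)
  n1 <- length(x1)
  stats <- apply(combn(length(pool), n1), 2, function(idx)
    mean(pool[idx]) - mean(pool[-idx]))
  mean(abs(stats) >= abs(stats[1])) # first assignment = observed labelling
}

# Pooled SAM permutation null over all proteins x all assignments.
oracle_sam_pooled <- function(X1, X2, s0) {
  d_of <- function(a, b) {
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    (mean(a) - mean(b)) / (se + s0)
  }
  n1 <- ncol(X1)
  pool <- c()
  d_obs <- numeric(nrow(X1))
  for (i in seq_len(nrow(X1))) {
    v <- c(X1[i, ], X2[i, ])
    null_i <- apply(combn(length(v), n1), 2, function(idx)
      d_of(v[idx], v[-idx]))
    pool <- c(pool, null_i)
    d_obs[i] <- d_of(X1[i, ], X2[i, ])
  }
  vapply(d_obs, function(d) mean(abs(pool) >= abs(d)), numeric(1))
}

# Partial AUC by explicit threshold enumeration and trapezoids, with linear
# interpolation at the FPR boundary.
oracle_pauc <- function(scores, truth, fpr_max) {
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- rbind(c(0, 0), t(vapply(th, function(s) {
    c(mean(scores[!truth] >= s), mean(scores[truth] >= s))
  }, numeric(2))))
  area <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    x0 <- pts[i, 1]; x1 <- pts[i + 1, 1]
    y0 <- pts[i, 2]; y1 <- pts[i + 1, 2]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

# Brute-force kNN imputed value for one missing cell: exhaustive pairwise
# Euclidean distances over shared observed columns.
oracle_knn_cell <- function(block, i, j, k) {
  target <- block[i, ]
  d <- rep(Inf, nrow(block))
  for (p in seq_len(nrow(block))) {
    if (p == i) next
    shared <- !is.na(target) & !is.na(block[p, ])
    if (any(shared))
      d[p] <- sqrt(sum((target[shared] - block[p, shared])^2))
  }
  elig <- which(is.finite(d) & !is.na(block[, j]))
  elig <- elig[order(d[elig], elig)]
  mean(block[elig[seq_len(min(k, length(elig)))], j])
}
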