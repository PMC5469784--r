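#' @name impute
#' @title Missing-value imputation methods
#'
#' @description Four imputation strategies for log-scale intensity matrices:
#' mean imputation (`impute_mean`), k-nearest-neighbour imputation
#' (`impute_knn`), abundance-distribution imputation (`impute_adi`) and
#' multiple imputation by chained equations (`impute_mice`). All methods are
#' applied within each group's replicate block (`by_group = TRUE`, the
#' default), never across groups, so imputed values cannot leak group
#' differences. Observed cells are never altered, and no `NA` is left behind
#' when the preconditions hold.
NULL

# Apply a block-level imputer to each group's replicate block (or the whole
# matrix when by_group = FALSE) and reassemble the ExpressionMatrix.
impute_by_block <- function(em, by_group, fun) {
  stopifnot(is_expression_matrix(em))
  v <- em$values
  blocks <- if (by_group) lapply(levels(em$groups), function(g)
    group_columns(em, g)) else list(seq_len(ncol(v)))
  for (cols in blocks)
    v[, cols] <- fun(v[, cols, drop = FALSE])
  em$values <- v
  em
}

#' Mean imputation
#'
#' Replaces each missing cell with the mean of the observed cells of its
#' protein (`axis = "row"`) or its replicate column (`axis = "column"`).
#'
#' @param em A log-scale `ExpressionMatrix`.
#' @param axis `"row"` (protein mean) or `"column"` (replicate mean).
#' @param by_group Impute within each group's replicate block (default).
#' @return The completed `ExpressionMatrix`.
#' @export
impute_mean <- function(em, axis = c("row", "column"), by_group = TRUE) {
  axis <- match.arg(axis)
  impute_by_block(em, by_group, function(block) {
    miss <- is.na(block)
    if (!any(miss)) return(block)
    if (axis == "row") {
      n_obs <- rowSums(!miss)
      bad <- which(miss & n_obs == 0, arr.ind = TRUE)
      if (nrow(bad))
        stop("protein(s) with no observed value in block: ",
             paste(unique(rownames(block)[bad[, 1]]), collapse = ", "))
      fill <- rowMeans(block, na.rm = TRUE)[row(block)]
    } else {
      n_obs <- colSums(!miss)
      bad <- which(miss & rep(n_obs == 0, each = nrow(block)))
      if (length(bad))
        stop("replicate(s) with no observed value in block: ",
             paste(unique(colnames(block)[col(block)[bad]]), collapse = ", "))
      fill <- colMeans(block, na.rm = TRUE)[col(block)]
    }
    block[miss] <- fill[miss]
    block
  })
}

#' k-nearest-neighbour imputation
#'
#' For each missing cell (protein i, replicate j), the k proteins nearest to
#' i by Euclidean distance over the replicates observed in both proteins —
#' restricted to proteins observed at replicate j — donate their replicate-j
#' values, and the missing cell is filled with their unweighted mean. When no
#' eligible neighbour exists the protein's own row mean is used as fallback,
#' and the block's replicate mean when the whole row is missing. Distances are plain Euclidean on the shared columns (not rescaled by the
#' number of shared columns).
#'
#' @param em A log-scale `ExpressionMatrix`.
#' @param k Number of neighbours (default 10).
#' @param by_group Impute within each group's replicate block (default).
#' @return The completed `ExpressionMatrix`.
#' @export
impute_knn <- function(em, k = 10, by_group = TRUE) {
  if (k < 1) stop("k must be >= 1")
  impute_by_block(em, by_group, function(block) {
    miss_idx <- which(is.na(block), arr.ind = TRUE)
    if (!nrow(miss_idx)) return(block)
    if (nrow(block) < 2) stop("kNN imputation needs >= 2 proteins")
    out <- block
    for (i in unique(miss_idx[, 1])) {
      target <- block[i, ]
      obs_t <- !is.na(target)
      # squared distance to every protein over columns observed in both
      d2 <- vapply(seq_len(nrow(block)), function(p) {
        shared <- obs_t & !is.na(block[p, ])
        if (p == i || !any(shared)) return(Inf)
        sum((target[shared] - block[p, shared])^2)
      }, numeric(1))
      for (j in miss_idx[miss_idx[, 1] == i, 2]) {
        elig <- which(is.finite(d2) & !is.na(block[, j]))
        if (length(elig) == 0) {
          out[i, j] <- if (any(obs_t)) mean(target[obs_t])
                       else mean(block[, j], na.rm = TRUE)
        } else {
          nb <- elig[order(d2[elig], elig)][seq_len(min(k, length(elig)))]
          out[i, j] <- mean(block[nb, j])
        }
      }
    }
    out
  })
}

#' Parameters for abundance-distribution imputation
#'
#' @param pool_fraction Fraction of observed proteins defining the abundance
#'   pool per replicate (default 0.25).
#' @param pool_tail Which tail of the abundance distribution supplies the
#'   pool: `"low"` (default — missing peptides are predominantly
#'   low-abundant) or `"high"`.
#' @param repeats Number of random imputations averaged (default 100).
#' @param seed RNG seed.
#' @return An `AdiParams` list.
#' @export
adi_params <- function(pool_fraction = 0.25, pool_tail = c("low", "high"),
                       repeats = 100, seed = 1L) {
  pool_tail <- match.arg(pool_tail)
  stopifnot(pool_fraction > 0, pool_fraction <= 1, repeats >= 1)
  structure(list(pool_fraction = pool_fraction, pool_tail = pool_tail,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "AdiParams")
}

# Pool mean/SD for one replicate column: sort observed values ascending and
# take the pool_fraction tail.
adi_pool_stats <- function(col_values, pool_fraction, pool_tail) {
  obs <- sort(col_values[!is.na(col_values)])
  if (length(obs) < 2)
    stop("replicate has fewer than 2 observed values")
  n_pool <- max(2L, round(pool_fraction * length(obs)))
  pool <- if (pool_tail == "low") utils::head(obs, n_pool)
          else utils::tail(obs, n_pool)
  c(mu = mean(pool), sigma = stats::sd(pool))
}

#' Abundance-distribution imputation
#'
#' Per replicate, a normal benchmark distribution `N(mu_j, sigma_j)` is
#' fitted to the abundance pool (by default the lowest-abundance quartile of
#' the observed values), each missing cell is drawn from that normal
#' truncated to positive values, and the whole imputation is repeated
#' `repeats` times with the per-cell average as the final result.
#'
#' @param em A log-scale `ExpressionMatrix`.
#' @param params An [adi_params()] object.
#' @param by_group Impute within each group's replicate block (default).
#' @return The completed `ExpressionMatrix`.
#' @export
impute_adi <- function(em, params = adi_params(), by_group = TRUE) {
  stopifnot(inherits(params, "AdiParams"))
  with_seed(params$seed, impute_by_block(em, by_group, function(block) {
    miss <- is.na(block)
    if (!any(miss)) return(block)
    for (j in seq_len(ncol(block))) {
      nj <- sum(miss[, j])
      if (nj == 0) next
      st <- adi_pool_stats(block[, j], params$pool_fraction, params$pool_tail)
      if (st["sigma"] == 0) {
        block[miss[, j], j] <- st["mu"]
      } else {
        draws <- matrix(rnorm_positive(nj * params$repeats, st["mu"],
                                       st["sigma"]), nj, params$repeats)
        block[miss[, j], j] <- rowMeans(draws)
      }
    }
    block
  }))
}

# Normal draws truncated to positive values by rejection sampling.
rnorm_positive <- function(n, mu, sigma) {
  x <- stats::rnorm(n, mu, sigma)
  while (any(neg <- x <= 0))
    x[neg] <- stats::rnorm(sum(neg), mu, sigma)
  x
}

#' Parameters for multiple imputation by chained equations
#'
#' @param m Number of imputations averaged (default 5).
#' @param max_iter Chained-equation sweeps per imputation (default 10).
#' @param seed RNG seed.
#' @return A `MiceParams` list.
#' @export
mice_params <- function(m = 5, max_iter = 10, seed = 1L) {
  stopifnot(m >= 1, max_iter >= 1)
  structure(list(m = as.integer(m), max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "MiceParams")
}

# One chained-equations completion of a block: initialize NAs with column
# means, then for max_iter sweeps regress each originally-incomplete column
# on the other columns (fit on rows where the target is observed, predictors
# from the current completed data), predict each NA and add a residual drawn
# from the empirical residual distribution.
mice_once <- function(block, max_iter) {
  miss <- is.na(block)
  cur <- block
  for (j in seq_len(ncol(cur)))
    cur[miss[, j], j] <- mean(block[, j], na.rm = TRUE)
  cols_na <- which(colSums(miss) > 0)
  for (it in seq_len(max_iter)) {
    for (j in cols_na) {
      obs <- !miss[, j]
      X <- cur[, -j, drop = FALSE]
      fit <- tryCatch(
        stats::lm.fit(cbind(1, X[obs, , drop = FALSE]), block[obs, j]),
        error = function(e) NULL)
      if (is.null(fit) || any(is.na(fit$coefficients))) {
        warning("singular regression design; falling back to column mean ",
                "for replicate ", colnames(block)[j])
        pred <- rep(mean(block[obs, j]), sum(miss[, j]))
        resid <- block[obs, j] - mean(block[obs, j])
      } else {
        pred <- drop(cbind(1, X[miss[, j], , drop = FALSE]) %*%
                       fit$coefficients)
        resid <- fit$residuals
      }
      delta <- resid[sample.int(length(resid), sum(miss[, j]),
                                replace = TRUE)]
      cur[miss[, j], j] <- pred + delta
    }
  }
  cur
}

#' Multiple imputation by chained equations
#'
#' Within each group's replicate block: missing cells are initialized with
#' column means; for `max_iter` sweeps each incomplete replicate is regressed
#' on the other replicates by ordinary least squares, every missing cell is
#' predicted from the regression, and a residual drawn from the empirical
#' residual distribution is added. The whole procedure is repeated `m` times
#' with independent randomness and the per-cell average of the `m` completed
#' matrices is returned.
#'
#' @param em A log-scale `ExpressionMatrix` whose blocks have >= 2 columns.
#' @param params A [mice_params()] object.
#' @param by_group Impute within each group's replicate block (default).
#' @return The completed `ExpressionMatrix`.
#' @export
impute_mice <- function(em, params = mice_params(), by_group = TRUE) {
  stopifnot(inherits(params, "MiceParams"))
  with_seed(params$seed, impute_by_block(em, by_group, function(block) {
    if (!anyNA(block)) return(block)
    if (ncol(block) < 2)
      stop("chained-equations imputation needs >= 2 replicates per block")
    if (any(colSums(!is.na(block)) < 2))
      stop("every replicate needs >= 2 observed values")
    acc <- matrix(0, nrow(block), ncol(block))
    for (r in seq_len(params$m))
      acc <- acc + mice_once(block, params$max_iter)
    out <- acc / params$m
    out[!is.na(block)] <- block[!is.na(block)]
    dimnames(out) <- dimnames(block)
    out
  }))
}

#' Sweep the number of imputations for chained-equations imputation
#'
#' Runs [impute_mice()] at each value of `m` and scores the completed matrix
#' against the true (pre-masking) matrix with [imputation_fidelity()]. The
#' default grid is the 48 consecutive integers 3--50 plus the nine larger
#' values 60, 80, 100, 150, 200, 300, 400, 600, 800 (57 values).
#'
#' @param true_em The complete `ExpressionMatrix` before masking.
#' @param masked_em The masked `ExpressionMatrix`.
#' @param m_values Integer vector of imputation counts.
#' @param max_iter Sweeps per imputation (default 10).
#' @param seed RNG seed; each `m` gets an independent derived seed.
#' @return A data frame with columns `m`, `r`, `ln_mad`, `ln_msd`.
#' @export
sweep_imputation_times <- function(true_em, masked_em,
                                   m_values = c(3:50, 60, 80, 100, 150, 200,
                                                300, 400, 600, 800),
                                   max_iter = 10, seed = 1L) {
  stopifnot(identical(dim(true_em$values), dim(masked_em$values)))
  rows <- lapply(m_values, function(m) {
    imp <- impute_mice(masked_em,
                       mice_params(m = m, max_iter = max_iter,
                                   seed = string_seed("msweep", seed, m)))
    fid <- imputation_fidelity(true_em, imp)
    data.frame(m = m, r = fid$r_overall, ln_mad = fid$ln_mad,
               ln_msd = fid$ln_msd)
  })
  do.call(rbind, rows)
}
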