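#' @name evaluate
#' @title Evaluation indexes
#'
#' @description Scoring of detection results against known truth (confusion
#' metrics, ROC/partial AUC, detection rate and mean rank) and of imputed
#' matrices against the pre-masking truth (per-replicate Pearson correlation,
#' mean absolute deviation, modified standard deviation).
NULL

#' Benjamini–Hochberg q-values
#'
#' Step-up adjusted p-values via [stats::p.adjust()]; `NA`s are passed
#' through and the adjustment uses the number of non-missing p-values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of q-values in input order.
#' @export
bh_qvalues <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Confusion counts and derived metrics at a cutoff
#'
#' @param calls Logical vector: protein called differentially expressed.
#' @param truth Logical vector of the same length: protein truly
#'   differentially expressed.
#' @return A `ConfusionCounts` list: `tp`, `fp`, `tn`, `fn`, and
#'   `tpr = TP/(TP+FN)`, `fpr = FP/(FP+TN)`, `fdr = FP/(TP+FP)`,
#'   `g_score = sqrt(TPR (1-FPR))`, `f_score` (harmonic mean of precision
#'   `1-FDR` and recall `TPR`). Zero-denominator metrics are `NA` with the
#'   reason recorded in `$reasons`.
#' @export
confusion_metrics <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("`calls` and `truth` must have the same length")
  calls <- as.logical(calls); truth <- as.logical(truth)
  keep <- !is.na(calls) & !is.na(truth)
  calls <- calls[keep]; truth <- truth[keep]
  tp <- sum(calls & truth); fp <- sum(calls & !truth)
  tn <- sum(!calls & !truth); fn <- sum(!calls & truth)
  reasons <- character()
  tpr <- if (tp + fn > 0) tp / (tp + fn) else {
    reasons <- c(reasons, "TPR undefined: no true positives in truth"); NA }
  fpr <- if (fp + tn > 0) fp / (fp + tn) else {
    reasons <- c(reasons, "FPR undefined: no true negatives in truth"); NA }
  fdr <- if (tp + fp > 0) fp / (tp + fp) else {
    reasons <- c(reasons, "FDR undefined: zero positive calls"); NA }
  g <- if (!is.na(tpr) && !is.na(fpr)) sqrt(tpr * (1 - fpr)) else NA_real_
  f <- if (!is.na(fdr) && !is.na(tpr) && (1 - fdr) + tpr > 0) {
    2 * (1 - fdr) * tpr / ((1 - fdr) + tpr)
  } else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, tpr = tpr, fpr = fpr,
                 fdr = fdr, g_score = g, f_score = f, reasons = reasons),
            class = "ConfusionCounts")
}

#' ROC curve and partial AUC
#'
#' Sweeps all thresholds of a ranking score (larger = more confidently
#' positive; pass `-p_value` for p-value rankings), grouping ties, and
#' integrates the ROC by trapezoids over `FPR <= fpr_max` with linear
#' interpolation at the boundary. The partial area is reported raw, so its
#' maximum is `fpr_max` itself (0.05 for the conventional specificity > 0.95
#' window); `normalized = TRUE` applies the McClish rescaling to `[0.5, 1]`.
#'
#' @param scores Numeric ranking scores, one per protein.
#' @param truth Logical truth vector.
#' @param fpr_max Upper FPR bound of the partial window (default 0.05).
#' @param normalized Report the McClish-standardized pAUC instead of the raw
#'   area (default `FALSE`).
#' @return A list with `roc` (data frame `fpr`, `tpr`, `threshold`), `pauc`,
#'   and `auc` (full area).
#' @export
roc_pauc <- function(scores, truth, fpr_max = 0.05, normalized = FALSE) {
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]; truth <- as.logical(truth[keep])
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  grp_end <- which(diff(s) != 0)
  cut_idx <- c(grp_end, length(s))        # ties grouped
  tpr <- cumsum(t)[cut_idx] / n_pos
  fpr <- cumsum(!t)[cut_idx] / n_neg
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, s[cut_idx]))
  auc_upto <- function(xmax) {
    x <- roc$fpr; y <- roc$tpr
    a <- 0
    for (i in seq_len(nrow(roc) - 1)) {
      x0 <- x[i]; x1 <- x[i + 1]
      if (x0 >= xmax) break
      y0 <- y[i]; y1 <- y[i + 1]
      if (x1 > xmax) {  # linear interpolation at the window boundary
        y1 <- y0 + (y1 - y0) * (xmax - x0) / (x1 - x0)
        x1 <- xmax
      }
      a <- a + (x1 - x0) * (y0 + y1) / 2
    }
    a
  }
  pauc <- auc_upto(fpr_max)
  if (normalized)
    pauc <- 0.5 * (1 + (pauc - fpr_max^2 / 2) / (fpr_max - fpr_max^2 / 2))
  list(roc = roc, pauc = pauc, auc = auc_upto(1))
}

#' Detection rate and mean rank of known positives in a top window
#'
#' Proteins are ranked most-significant-first by p-value, with ties broken by
#' placing known positives first (the sequential-labelling convention of
#' spike-in benchmarks, where the spike-in proteins head the protein list).
#' Within the top `window` positions, `N` is the number of true positives,
#' `RS` the sum of their positions, `DR = N/window` and `MR = RS/N`.
#'
#' @param p_values Numeric p-values (smaller = more significant).
#' @param truth Logical truth vector.
#' @param window Top-list size (default 32, a spike-in panel size).
#' @return A `RankingEvaluation` list: `n`, `rank_sum`, `dr`, `mr` (`NA` when
#'   no true positive falls in the window).
#' @export
detection_rate_mean_rank <- function(p_values, truth, window = 32) {
  if (window < 1) stop("window must be >= 1")
  if (window > length(p_values)) stop("window exceeds number of proteins")
  truth <- as.logical(truth)
  if (!any(truth, na.rm = TRUE)) stop("no true positives in the dataset")
  ord <- order(p_values, !truth, na.last = TRUE)  # ties: positives first
  top <- truth[ord][seq_len(window)]
  top[is.na(top)] <- FALSE
  n <- sum(top)
  rs <- sum(seq_len(window)[top])
  structure(list(n = n, rank_sum = rs, dr = n / window,
                 mr = if (n > 0) rs / n else NA_real_),
            class = "RankingEvaluation")
}

#' Fidelity of an imputed matrix to the pre-masking truth
#'
#' Per replicate column: the absolute Pearson correlation `r_j` between the
#' true and post-imputation columns; the overall `r` is the minimum over
#' replicates. Deviations `dy_i = |true - imputed|` define, per replicate,
#' `MAD = sum(dy)/n0` and `MSD = sqrt(sum(dy^2)/n0)` where `n0` counts
#' proteins with non-zero deviation (both 0 when `n0 = 0`). For reporting,
#' `ln(MAD)` and `ln(MSD)` are averaged over replicates.
#'
#' @param true_em,imputed_em Congruent `ExpressionMatrix` objects (or bare
#'   matrices) on the same scale.
#' @return An `ImputationFidelity` list: `r_per_replicate`, `r_overall`,
#'   `mad`, `msd` (per-replicate vectors), `n0` (total), `ln_mad`, `ln_msd`
#'   (replicate means; `-Inf` when a replicate has no deviation).
#' @export
imputation_fidelity <- function(true_em, imputed_em) {
  tv <- if (is_expression_matrix(true_em)) true_em$values else true_em
  iv <- if (is_expression_matrix(imputed_em)) imputed_em$values else imputed_em
  if (!identical(dim(tv), dim(iv)))
    stop("true and imputed matrices are not congruent")
  if (anyNA(iv)) stop("imputed matrix still contains missing values")
  r <- mad <- msd <- numeric(ncol(tv))
  n0_total <- 0L
  for (j in seq_len(ncol(tv))) {
    if (stats::sd(tv[, j]) == 0 || stats::sd(iv[, j]) == 0)
      stop("zero variance in replicate ", colnames(tv)[j],
           ": correlation undefined")
    r[j] <- abs(stats::cor(tv[, j], iv[, j]))
    dy <- abs(tv[, j] - iv[, j])
    n0 <- sum(dy > 0)
    n0_total <- n0_total + n0
    mad[j] <- if (n0 > 0) sum(dy) / n0 else 0
    msd[j] <- if (n0 > 0) sqrt(sum(dy^2) / n0) else 0
  }
  structure(list(r_per_replicate = r, r_overall = min(r), mad = mad,
                 msd = msd, n0 = n0_total,
                 ln_mad = mean(log(mad)), ln_msd = mean(log(msd))),
            class = "ImputationFidelity")
}

#' Average confusion metrics over the pairs of a design
#'
#' Computes [confusion_metrics()] per pair at a q-value cutoff and returns
#' the unweighted mean of TPR, FPR and FDR over pairs. Pairs whose FDR is
#' undefined (zero positive calls) are excluded from the FDR mean; their
#' count is reported.
#'
#' @param results Long results data frame from [run_all()] (columns `pair`,
#'   `protein_id`, `q_value`), for a single method.
#' @param truth Named logical vector of true DEP labels (names = protein id).
#' @param cutoff q-value cutoff (default 0.05).
#' @return A one-row data frame: `tpr`, `fpr`, `fdr`, `n_pairs`,
#'   `n_fdr_excluded`.
#' @export
pairwise_summary <- function(results, truth, cutoff = 0.05) {
  pairs <- unique(results$pair)
  if (!length(pairs)) stop("no pairs in results")
  per <- lapply(pairs, function(pn) {
    r <- results[results$pair == pn, ]
    confusion_metrics(!is.na(r$q_value) & r$q_value < cutoff,
                      truth[r$protein_id])
  })
  fdrs <- vapply(per, `[[`, numeric(1), "fdr")
  data.frame(tpr = mean(vapply(per, `[[`, numeric(1), "tpr")),
             fpr = mean(vapply(per, `[[`, numeric(1), "fpr")),
             fdr = mean(fdrs, na.rm = TRUE),
             n_pairs = length(pairs),
             n_fdr_excluded = sum(is.na(fdrs)))
}
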