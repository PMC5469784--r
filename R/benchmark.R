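#' Configuration of the benchmark grid
#'
#' Bundles every stage's parameters for [run_benchmark()] and
#' [run_m_sweep()]: the simulator settings, the missing-value fractions, the
#' imputation arms (always including `"ignore"`, i.e. testing on the masked
#' data directly), the detection methods, and the evaluation cutoffs.
#'
#' @param sim A [simulation_params()] object.
#' @param fractions Missing-value fractions of the dataset series.
#' @param imputations Subset of `c("ignore", "mean", "knn", "adi", "mice")`.
#' @param detections Subset of `c("welch", "perm", "sam", "rots")`.
#' @param cutoffs Significance cutoffs for the confusion metrics.
#' @param cutoff_type Apply cutoffs to `"q"` (BH-adjusted, default) or `"p"`.
#' @param knn_k,adi,mice,sam,rots,perm_n Per-method parameters (seeds inside
#'   `adi`/`mice` are replaced by per-arm seeds derived from `master_seed`).
#' @param dr_window Top-window size for detection rate / mean rank; `NULL`
#'   (default) uses the number of true DEPs.
#' @param m_values m grid for [run_m_sweep()] (default: the 57-value grid of
#'   [sweep_imputation_times()]).
#' @param master_seed Seed from which every arm's RNG stream is derived.
#' @param out_dir Output directory for TSV/manifest files, or `NULL` to only
#'   return tables.
#' @return A `BenchmarkConfig` list.
#' @export
benchmark_config <- function(sim = simulation_params(),
                             fractions = seq(0.05, 0.45, by = 0.05),
                             imputations = c("ignore", "mean", "knn", "adi",
                                             "mice"),
                             detections = c("welch", "perm", "sam", "rots"),
                             cutoffs = c(0.05, 0.01),
                             cutoff_type = c("q", "p"),
                             knn_k = 10, adi = adi_params(),
                             mice = mice_params(), sam = sam_params(),
                             rots = rots_params(), perm_n = 10000,
                             dr_window = NULL,
                             m_values = c(3:50, 60, 80, 100, 150, 200, 300,
                                          400, 600, 800),
                             master_seed = 1L, out_dir = NULL) {
  imputations <- match.arg(imputations, several.ok = TRUE)
  detections <- match.arg(detections, several.ok = TRUE)
  cutoff_type <- match.arg(cutoff_type)
  stopifnot(length(fractions) >= 1, length(cutoffs) >= 1)
  structure(list(sim = sim, fractions = fractions, imputations = imputations,
                 detections = detections, cutoffs = cutoffs,
                 cutoff_type = cutoff_type, knn_k = knn_k, adi = adi,
                 mice = mice, sam = sam, rots = rots, perm_n = perm_n,
                 dr_window = dr_window, m_values = m_values,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "BenchmarkConfig")
}

# Hash of the scientific configuration only: the output location must not
# change the recorded identity of a run.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  string_seed(paste(deparse(cfg), collapse = ""))
}

impute_arm <- function(masked, method, config, seed) {
  switch(method,
    ignore = masked,
    mean = impute_mean(masked, axis = "column"),
    knn = impute_knn(masked, k = config$knn_k),
    adi = impute_adi(masked, adi_params(config$adi$pool_fraction,
                                        config$adi$pool_tail,
                                        config$adi$repeats, seed = seed)),
    mice = impute_mice(masked, mice_params(config$mice$m,
                                           config$mice$max_iter,
                                           seed = seed)))
}

#' Run the full benchmark grid
#'
#' Simulates one complete two-group dataset, masks it at every requested
#' missing-value fraction with the graded MNAR mechanism, imputes each masked
#' dataset with every imputation arm, detects DEPs with every detection
#' method, and scores everything. Results: one metrics row per (fraction,
#' imputation, detection, cutoff) and one fidelity row per (fraction,
#' imputation method other than `"ignore"`). Undefined metrics are emitted as
#' `NA` with a reason, never dropped. Every random stage draws from a stream
#' derived from `master_seed` and the arm's name, so re-running reproduces
#' every table exactly and adding an arm perturbs no other arm.
#'
#' @param config A [benchmark_config()].
#' @return A list with `metrics`, `fidelity` (data frames) and `manifest`;
#'   when `config$out_dir` is set, also written as `metrics.tsv`,
#'   `fidelity.tsv` and `manifest.json`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "BenchmarkConfig"))
  sim_par <- config$sim
  sim_par$seed <- string_seed("simulate", config$master_seed)
  sim <- generate_complete(sim_par)
  grades <- assign_grades(sim$matrix)
  truth <- sim$truth
  pair <- levels(sim$matrix$groups)[1:2]
  metrics <- list(); fidelity <- list(); arm_seeds <- list()
  failures <- list()
  for (frac in config$fractions) {
    fkey <- sprintf("mv%02.0f", 100 * frac)
    mask_seed <- string_seed("mask", config$master_seed, fkey)
    masked <- inject_missing(sim$matrix, grades,
                             missingness_params(frac, seed = mask_seed))
    for (imp in config$imputations) {
      imp_seed <- string_seed("impute", config$master_seed, fkey, imp)
      arm_seeds[[paste(fkey, imp, sep = ":")]] <- imp_seed
      dat <- tryCatch(impute_arm(masked, imp, config, imp_seed),
                      error = function(e) e)
      if (inherits(dat, "error")) {
        failures[[paste(fkey, imp, sep = ":")]] <- conditionMessage(dat)
        next
      }
      if (imp != "ignore") {
        fid <- imputation_fidelity(sim$matrix, dat)
        fidelity[[paste(fkey, imp)]] <-
          data.frame(mv_fraction = frac, imputation = imp,
                     r = fid$r_overall, ln_mad = fid$ln_mad,
                     ln_msd = fid$ln_msd)
      }
      for (meth in config$detections) {
        det_seed <- string_seed("detect", config$master_seed, fkey, imp, meth)
        res <- tryCatch(switch(meth,
          welch = welch_t(dat, pair),
          perm  = permutation_test(dat, pair, config$perm_n, seed = det_seed),
          sam   = sam_test(dat, pair, config$sam, seed = det_seed),
          rots  = rots_test(dat, pair, config$rots, seed = det_seed)),
          error = function(e) e)
        if (inherits(res, "error")) {
          for (cut in config$cutoffs)
            metrics[[paste(fkey, imp, meth, cut)]] <- data.frame(
              mv_fraction = frac, imputation = imp, method = meth,
              cutoff = cut, tpr = NA, fpr = NA, fdr = NA, g_score = NA,
              f_score = NA, pauc = NA, dr = NA, mr = NA,
              note = conditionMessage(res))
          next
        }
        res$q_value <- bh_qvalues(res$p_value)
        tr <- truth$de_labels[res$protein_id]
        roc <- roc_pauc(-res$p_value, tr)
        win <- if (is.null(config$dr_window)) sum(tr) else config$dr_window
        drmr <- detection_rate_mean_rank(res$p_value, tr, window = win)
        crit <- if (config$cutoff_type == "q") res$q_value else res$p_value
        for (cut in config$cutoffs) {
          cm <- confusion_metrics(!is.na(crit) & crit < cut, tr)
          metrics[[paste(fkey, imp, meth, cut)]] <- data.frame(
            mv_fraction = frac, imputation = imp, method = meth,
            cutoff = cut, tpr = cm$tpr, fpr = cm$fpr, fdr = cm$fdr,
            g_score = cm$g_score, f_score = cm$f_score, pauc = roc$pauc,
            dr = drmr$dr, mr = drmr$mr,
            note = if (length(cm$reasons))
              paste(cm$reasons, collapse = "; ") else NA_character_)
        }
      }
    }
  }
  out <- list(metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
              fidelity = do.call(rbind, c(fidelity, make.row.names = FALSE)),
              manifest = list(master_seed = config$master_seed,
                              config_hash = config_hash(config),
                              arm_seeds = arm_seeds, failures = failures))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv <- function(df, f)
      utils::write.table(format(df, digits = 15), file.path(config$out_dir, f),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_tsv(out$metrics, "metrics.tsv")
    if (!is.null(out$fidelity)) write_tsv(out$fidelity, "fidelity.tsv")
    jsonlite::write_json(out$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Sweep the number of chained-equation imputations over the dataset series
#'
#' For each missing-value fraction and each `m` in the configured grid, runs
#' [sweep_imputation_times()] on the masked dataset and collects the fidelity
#' table (the default grid yields 57 rows per fraction).
#'
#' @param config A [benchmark_config()].
#' @return A data frame with columns `mv_fraction`, `m`, `r`, `ln_mad`,
#'   `ln_msd`; also written as `msweep.tsv` when `config$out_dir` is set.
#' @export
run_m_sweep <- function(config) {
  stopifnot(inherits(config, "BenchmarkConfig"))
  sim_par <- config$sim
  sim_par$seed <- string_seed("simulate", config$master_seed)
  sim <- generate_complete(sim_par)
  grades <- assign_grades(sim$matrix)
  rows <- lapply(config$fractions, function(frac) {
    fkey <- sprintf("mv%02.0f", 100 * frac)
    masked <- inject_missing(
      sim$matrix, grades,
      missingness_params(frac,
                         seed = string_seed("mask", config$master_seed, fkey)))
    tab <- sweep_imputation_times(
      sim$matrix, masked, m_values = config$m_values,
      max_iter = config$mice$max_iter,
      seed = string_seed("msweep", config$master_seed, fkey))
    cbind(mv_fraction = frac, tab)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(format(out, digits = 15),
                       file.path(config$out_dir, "msweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
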