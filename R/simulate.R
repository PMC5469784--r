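#' Parameters of the spike-in-style simulator
#'
#' The generator emulates a two-group label-free spike-in experiment on the
#' natural-log scale: a background population of proteins at a 1:1 abundance
#' ratio between groups and a differentially expressed (DE) population whose
#' second-group abundance is shifted by `log_fold_change` (the default,
#' `ln 3`, mirrors a 1:3 spike-in ratio).
#'
#' @param n_proteins Number of proteins (default 1000).
#' @param n_replicates Technical replicates per group (default 3).
#' @param frac_de Fraction of proteins that are true DEPs (default 0.3,
#'   roughly the spike-in fraction of a HeLa + E. coli benchmark mixture).
#' @param log_fold_change Additive log-scale effect for DEPs (default `log(3)`).
#' @param baseline_mean,baseline_sd Mean and SD of per-protein baseline
#'   log-intensities (defaults 21 and 2: natural-log LFQ intensities).
#' @param noise_sd Replicate-to-replicate technical noise SD on the log scale
#'   (default 0.3).
#' @param seed RNG seed.
#' @return A `SimulationParams` list.
#' @export
simulation_params <- function(n_proteins = 1000, n_replicates = 3,
                              frac_de = 0.3, log_fold_change = log(3),
                              baseline_mean = 21, baseline_sd = 2,
                              noise_sd = 0.3, seed = 1L) {
  stopifnot(frac_de >= 0, frac_de <= 1,
            n_proteins * n_replicates >= 10,
            baseline_sd >= 0, noise_sd >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 frac_de = frac_de, log_fold_change = log_fold_change,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "SimulationParams")
}

#' Parameters of the graded missing-value mechanism
#'
#' Missingness is abundance-dependent (MNAR): within each replicate the
#' proteins are split by abundance into grades I (low), II (medium) and III
#' (high) in proportion `grade_protein_ratio`, and the missing values are
#' allocated to the grades in proportion `grade_na_ratio`, so low-abundance
#' observations are preferentially lost.
#'
#' @param mv_fraction Overall fraction of observations set missing, in
#'   `[0, 1)`.
#' @param grade_protein_ratio Three-way split of proteins by abundance
#'   (default `c(3, 4, 3)`).
#' @param grade_na_ratio Three-way split of the NA budget across grades
#'   I/II/III (default `c(6, 3, 1)`).
#' @param mechanism `"graded"` (default, the abundance-dependent scheme) or
#'   `"mcar"`, a uniform missing-completely-at-random mode kept only as a
#'   testing baseline.
#' @param seed RNG seed.
#' @return A `MissingnessParams` list.
#' @export
missingness_params <- function(mv_fraction, grade_protein_ratio = c(3, 4, 3),
                               grade_na_ratio = c(6, 3, 1),
                               mechanism = c("graded", "mcar"), seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(mv_fraction >= 0, mv_fraction < 1,
            length(grade_protein_ratio) == 3, all(grade_protein_ratio >= 0),
            sum(grade_protein_ratio) > 0,
            length(grade_na_ratio) == 3, all(grade_na_ratio >= 0),
            sum(grade_na_ratio) > 0)
  structure(list(mv_fraction = mv_fraction,
                 grade_protein_ratio = grade_protein_ratio,
                 grade_na_ratio = grade_na_ratio, mechanism = mechanism,
                 seed = as.integer(seed)),
            class = "MissingnessParams")
}

#' Generate a complete two-group dataset with known DEPs
#'
#' @param params A [simulation_params()] object.
#' @return A list with elements `matrix` (a complete log-scale
#'   [expression_matrix()] with groups `g1`, `g2`) and `truth`
#'   (a `SimulationTruth` list: `de_labels` named logical, `true_values` the
#'   complete matrix, `grades` filled in later by [assign_grades()]).
#' @export
generate_complete <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  p <- params
  with_seed(p$seed, {
    ids <- sprintf("P%04d", seq_len(p$n_proteins))
    base <- stats::rnorm(p$n_proteins, p$baseline_mean, p$baseline_sd)
    n_de <- round(p$frac_de * p$n_proteins)
    de <- rep(FALSE, p$n_proteins)
    de[sample.int(p$n_proteins, n_de)] <- TRUE
    nrep <- p$n_replicates
    mu <- cbind(matrix(base, p$n_proteins, nrep),
                matrix(base + ifelse(de, p$log_fold_change, 0),
                       p$n_proteins, nrep))
    vals <- mu + stats::rnorm(length(mu), 0, p$noise_sd)
    dimnames(vals) <- list(ids, c(paste0("g1_r", seq_len(nrep)),
                                  paste0("g2_r", seq_len(nrep))))
    em <- expression_matrix(vals, groups = rep(c("g1", "g2"), each = nrep),
                            scale = "log")
    names(de) <- ids
    truth <- structure(list(de_labels = de, true_values = vals,
                            grades = NULL),
                       class = "SimulationTruth")
    list(matrix = em, truth = truth)
  })
}

#' Assign abundance grades per replicate
#'
#' Within each replicate (column) independently, proteins are sorted by
#' expression level in ascending order and split into grade I (lowest), II,
#' and III (highest) in proportion `grade_protein_ratio`. The grade is a
#' property of a (protein, replicate) observation — a protein may hold
#' different grades in different replicates.
#'
#' @param em A complete (no missing cells) `ExpressionMatrix`.
#' @param grade_protein_ratio Three-way abundance split (default `c(3, 4, 3)`).
#' @return An integer matrix of the same dimensions as `em$values` with
#'   entries 1, 2, 3 for grades I, II, III.
#' @export
assign_grades <- function(em, grade_protein_ratio = c(3, 4, 3)) {
  stopifnot(is_expression_matrix(em))
  v <- em$values
  if (anyNA(v)) stop("assign_grades requires a complete matrix")
  counts <- largest_remainder(nrow(v), grade_protein_ratio)
  grades <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  for (j in seq_len(ncol(v))) {
    ord <- order(v[, j])  # ascending abundance; stable on ties
    grades[ord, j] <- rep.int(1:3, counts)
  }
  grades
}

#' Inject missing values by abundance grade
#'
#' Applies the graded MNAR mechanism to each group's replicate block
#' independently. Within a block of `n_proteins x n_replicates` cells, the
#' total NA count is `round(mv_fraction * cells)`, split across grades
#' I/II/III by `grade_na_ratio` with largest-remainder rounding, and the
#' masked cells are drawn uniformly at random within each grade.
#'
#' @param em A complete log-scale `ExpressionMatrix`.
#' @param grades Grade matrix from [assign_grades()] (same dimensions).
#' @param params A [missingness_params()] object.
#' @return `em` with the selected cells set to `NA`.
#' @export
inject_missing <- function(em, grades, params) {
  stopifnot(is_expression_matrix(em), inherits(params, "MissingnessParams"),
            identical(dim(grades), dim(em$values)))
  if (anyNA(em$values)) stop("inject_missing expects a complete matrix")
  v <- em$values
  with_seed(params$seed, {
    for (g in levels(em$groups)) {
      cols <- group_columns(em, g)
      block_cells <- nrow(v) * length(cols)
      total_na <- round(params$mv_fraction * block_cells)
      if (params$mechanism == "mcar") {
        pick <- sample.int(block_cells, total_na)
        block <- v[, cols, drop = FALSE]
        block[pick] <- NA_real_
        v[, cols] <- block
        next
      }
      per_grade <- largest_remainder(total_na, params$grade_na_ratio)
      for (gr in 1:3) {
        idx <- which(grades[, cols, drop = FALSE] == gr)
        if (per_grade[gr] > length(idx))
          stop(sprintf(
            "group %s: %d NAs requested in grade %s but only %d cells",
            g, per_grade[gr], c("I", "II", "III")[gr], length(idx)))
        if (per_grade[gr] > 0) {
          pick <- idx[sample.int(length(idx), per_grade[gr])]
          block <- v[, cols, drop = FALSE]
          block[pick] <- NA_real_
          v[, cols] <- block
        }
      }
    }
    em$values <- v
    em
  })
}

#' Build a series of masked datasets over missing-value fractions
#'
#' One masked copy of `em` per fraction, with per-fraction seeds derived from
#' `params$seed` so the series is reproducible and extensible.
#'
#' @param em A complete log-scale `ExpressionMatrix`.
#' @param grades Grade matrix from [assign_grades()].
#' @param fractions Missing-value fractions (default `seq(0.05, 0.45, 0.05)`,
#'   the usual 5--45% sweep).
#' @param params A [missingness_params()] whose `mv_fraction` is ignored;
#'   its ratios and seed drive every member of the series.
#' @return Named list of masked `ExpressionMatrix` objects, one per fraction.
#' @export
build_mv_series <- function(em, grades, fractions = seq(0.05, 0.45, by = 0.05),
                            params = missingness_params(0)) {
  stopifnot(all(fractions >= 0), all(fractions < 1))
  out <- lapply(seq_along(fractions), function(i) {
    p <- missingness_params(fractions[i], params$grade_protein_ratio,
                            params$grade_na_ratio,
                            seed = string_seed("mv_series", params$seed,
                                               format(fractions[i])))
    inject_missing(em, grades, p)
  })
  names(out) <- sprintf("mv%02.0f", 100 * fractions)
  out
}
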