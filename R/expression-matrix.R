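#' Protein-by-replicate expression matrix
#'
#' The central container of the package: a numeric matrix of intensities with
#' one row per protein and one column per technical replicate, a group label
#' for every column, and a scale flag. Missing (non-quantified) cells are
#' `NA`. On `scale = "raw"` all observed values are strictly positive; on
#' `scale = "log"` (natural log) they are finite reals.
#'
#' @param values Numeric matrix; rownames are taken as protein ids (or
#'   supplied via `protein_ids`).
#' @param groups Character or factor of length `ncol(values)` mapping each
#'   column to its experimental group.
#' @param scale `"raw"` or `"log"`.
#' @param protein_ids Optional character vector of unique protein ids;
#'   overrides `rownames(values)`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (named numeric matrix), `groups` (factor, one level per group,
#'   in order of first appearance) and `scale`.
#' @examples
#' m <- matrix(rlnorm(12, 14), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("R", 1:4)))
#' em <- expression_matrix(m, groups = c("A", "A", "B", "B"), scale = "raw")
#' em
#' @export
expression_matrix <- function(values, groups, scale = c("raw", "log"),
                              protein_ids = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.null(protein_ids)) rownames(values) <- protein_ids
  if (is.null(rownames(values)))
    rownames(values) <- paste0("protein_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  if (length(groups) != ncol(values))
    stop("`groups` must have one label per column")
  groups <- factor(as.character(groups), levels = unique(as.character(groups)))
  em <- structure(list(values = values, groups = groups, scale = scale),
                  class = "ExpressionMatrix")
  validate_expression_matrix(em)
  em
}

#' @rdname expression_matrix
#' @param x,em An `ExpressionMatrix`.
#' @export
is_expression_matrix <- function(x) inherits(x, "ExpressionMatrix")

validate_expression_matrix <- function(em) {
  v <- em$values
  ids <- rownames(v)
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  obs <- v[!is.na(v)]
  if (em$scale == "raw" && any(obs <= 0))
    stop("raw-scale matrix contains non-positive observed values")
  if (em$scale == "log" && any(!is.finite(obs)))
    stop("log-scale matrix contains non-finite observed values")
  invisible(em)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("ExpressionMatrix: %d proteins x %d replicates (%s scale)\n",
              nrow(v), ncol(v), x$scale))
  cat(sprintf("groups: %s\n",
              paste(sprintf("%s (n=%d)", levels(x$groups),
                            tabulate(x$groups)), collapse = ", ")))
  cat(sprintf("missing: %d / %d cells (%.1f%%)\n", sum(is.na(v)), length(v),
              100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Column indices of one group
#'
#' @param em An `ExpressionMatrix`.
#' @param group A group label.
#' @return Integer vector of column indices belonging to `group`.
#' @export
group_columns <- function(em, group) {
  if (!group %in% levels(em$groups))
    stop("unknown group: ", group)
  which(em$groups == group)
}

#' Pairs of groups to test
#'
#' A design is an ordered set of group labels plus the ordered pairs to be
#' contrasted. The default pairing is adjacent pairs (A-B, B-C, ...), the
#' usual layout for concentration-series spike-in studies.
#'
#' @param group_labels Ordered character vector of group labels.
#' @param pairs List of length-2 character vectors; default adjacent pairs.
#' @return A `GroupDesign` list with `group_labels` and `pairs`.
#' @export
group_design <- function(group_labels, pairs = NULL) {
  group_labels <- as.character(group_labels)
  if (anyDuplicated(group_labels)) stop("duplicate group labels")
  if (is.null(pairs)) {
    if (length(group_labels) < 2) stop("need at least two groups")
    pairs <- Map(c, group_labels[-length(group_labels)], group_labels[-1])
  }
  pairs <- lapply(pairs, as.character)
  key <- vapply(pairs, paste, "", collapse = "\r")
  if (anyDuplicated(key)) stop("duplicate pairs in design")
  for (p in pairs) {
    if (length(p) != 2 || !all(p %in% group_labels))
      stop("pair must be two existing group labels: ",
           paste(p, collapse = "-"))
  }
  structure(list(group_labels = group_labels, pairs = pairs),
            class = "GroupDesign")
}

#' Read a protein intensity table
#'
#' Reads a tab-separated text file whose first column holds protein ids and
#' whose remaining columns hold raw intensities. Empty cells, `"NA"`, and
#' non-positive values (a zero label-free quantification intensity means the
#' protein was not quantified) become missing.
#'
#' @param path Path to a TSV file with a header row.
#' @param group_map Named character vector mapping column names to group
#'   labels; must cover every intensity column.
#' @return A raw-scale [expression_matrix()].
#' @export
read_matrix <- function(path, group_map) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("no data rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncols <- length(header)
  if (ncols < 2) stop("header must contain protein id plus >=1 sample column")
  sample_names <- header[-1]
  ids <- character(length(lines) - 1)
  vals <- matrix(NA_real_, length(lines) - 1, ncols - 1)
  for (i in seq_along(ids)) {
    row <- fields[[i + 1]]
    if (length(row) != ncols)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1, ncols, length(row)))
    ids[i] <- row[1]
    cells <- row[-1]
    missing <- cells == "" | cells == "NA"
    num <- suppressWarnings(as.numeric(cells))
    bad <- !missing & is.na(num)
    if (any(bad))
      stop(sprintf("line %d: non-numeric value '%s' in column '%s'",
                   i + 1, cells[which(bad)[1]], sample_names[which(bad)[1]]))
    num[missing | num <= 0] <- NA_real_  # zero/negative LFQ = not quantified
    vals[i, ] <- num
  }
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!all(sample_names %in% names(group_map)))
    stop("group_map is missing columns: ",
         paste(setdiff(sample_names, names(group_map)), collapse = ", "))
  dimnames(vals) <- list(ids, sample_names)
  expression_matrix(vals, groups = unname(group_map[sample_names]),
                    scale = "raw")
}

#' Write a protein intensity table
#'
#' Inverse of [read_matrix()]: values are printed with 17 significant digits
#' so that a read/write round trip is bit-exact; missing cells are written as
#' `"NA"`.
#'
#' @param em An `ExpressionMatrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(em, path) {
  v <- em$values
  txt <- matrix(sprintf("%.17g", v), nrow(v))
  txt[is.na(v)] <- "NA"
  lines <- c(paste(c("protein_id", colnames(v)), collapse = "\t"),
             paste(rownames(v), apply(txt, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a column-to-group map from a YAML config
#'
#' The config holds a `groups:` mapping of column name to group label.
#'
#' @param path YAML file path.
#' @return Named character vector suitable for [read_matrix()]'s `group_map`.
#' @export
read_group_map <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups)) stop("config has no `groups:` mapping")
  unlist(cfg$groups)
}

#' Natural-log transform
#'
#' @param em A raw-scale `ExpressionMatrix`.
#' @return The matrix on natural-log scale; the missingness pattern is
#'   unchanged.
#' @export
log_transform <- function(em) {
  stopifnot(is_expression_matrix(em))
  if (em$scale != "raw") stop("matrix is already on log scale")
  em$values <- log(em$values)
  em$scale <- "log"
  validate_expression_matrix(em)
}

#' Median normalization
#'
#' Shifts each column additively so that every column median (over observed
#' cells) equals the grand median of the original column medians. Because the
#' shift is additive on the log scale this is the usual median normalization
#' of log-intensities.
#'
#' @param em A log-scale `ExpressionMatrix`.
#' @return The normalized matrix.
#' @export
median_normalize <- function(em) {
  stopifnot(is_expression_matrix(em))
  if (em$scale != "log") stop("median_normalize expects a log-scale matrix")
  v <- em$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0))
    stop("column(s) with no observed values: ",
         paste(colnames(v)[n_obs == 0], collapse = ", "))
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  target <- stats::median(med)
  em$values <- sweep(v, 2, med - target)
  em
}
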