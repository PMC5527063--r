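#' Construct an expression table
#'
#' The package's expression container is a tidy tibble with one row per
#' feature and sample: columns `feature_id`, `condition` (a factor whose
#' level order is the period order — trends are read along it), `replicate`,
#' `abundance` (FPKM for mRNA/lncRNA, TPM for miRNA) and `feature_class`.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns.
#' @param design Tibble/data frame with columns `sample`, `condition`,
#'   `replicate`, one row per column of `values`, in column order.
#' @param feature_class One of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param conditions Character vector giving the period order; defaults to
#'   order of first appearance in `design$condition`.
#'
#' @return A tibble of class `cerna_expr`.
#' @export
expression_matrix <- function(values, design, feature_class,
                              conditions = NULL) {
  feature_class <- match.arg(feature_class, c("mRNA", "lncRNA", "miRNA"))
  design <- as_tibble(design)
  stopifnot(all(c("sample", "condition", "replicate") %in% names(design)))
  if (ncol(values) != nrow(design)) {
    abort("`values` must have one column per design row.")
  }
  if (is.null(rownames(values))) {
    abort("`values` must carry feature ids as rownames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort(sprintf(
      "duplicated feature id(s): %s",
      paste(unique(rownames(values)[duplicated(rownames(values))]),
            collapse = ", ")
    ))
  }
  conditions <- conditions %||% unique(as.character(design$condition))
  expr <- as_tibble(values, rownames = "feature_id") |>
    pivot_longer(-"feature_id", names_to = "sample", values_to = "abundance") |>
    left_join(design, by = "sample") |>
    mutate(
      condition = factor(.data$condition, levels = conditions),
      replicate = as.character(.data$replicate),
      feature_class = feature_class
    ) |>
    select("feature_id", "condition", "replicate", "abundance",
           "feature_class")
  validate_expression(expr)
}

validate_expression <- function(expr) {
  if (any(is.na(expr$abundance)) || any(!is.finite(expr$abundance))) {
    abort("abundances must be finite and non-missing.")
  }
  if (any(expr$abundance < 0)) {
    bad <- expr$feature_id[expr$abundance < 0][1]
    abort(sprintf("negative abundance for feature '%s'.", bad))
  }
  if (any(is.na(expr$condition))) {
    abort("every sample must map to a known condition.")
  }
  dup <- expr |>
    count(.data$feature_id, .data$condition, .data$replicate) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicated expression rows for feature '%s'.",
                  dup$feature_id[1]))
  }
  class(expr) <- c("cerna_expr", class(expr))
  expr
}

#' Read and write expression matrices
#'
#' The on-disk format is a tab-delimited table with a header row of sample
#' labels and feature ids in the first column. `design` maps sample labels to
#' (condition, replicate); when omitted, labels of the form
#' `<condition>_<replicate>` are parsed. Values must be finite and
#' non-negative; malformed numeric cells and duplicated feature ids are
#' errors, not silent coercions. The write/read round trip is lossless.
#'
#' @param path Path of the TSV file.
#' @param feature_class One of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param design Optional tibble with columns `sample`, `condition`,
#'   `replicate`.
#' @param conditions Optional character vector fixing the period order.
#' @return `read_expression()` returns a `cerna_expr` tibble;
#'   `write_expression()` returns `path` invisibly.
#' @export
read_expression <- function(path, feature_class, design = NULL,
                            conditions = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2) abort(sprintf("'%s': expected feature id column plus at least one sample column.", path))
  ids <- raw[[1]]
  samples <- names(raw)[-1]
  num <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(ids, samples))
  if (any(is.na(num))) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "'%s': malformed numeric value at feature '%s', sample '%s'.",
      path, ids[idx[1]], samples[idx[2]]
    ))
  }
  if (is.null(design)) {
    m <- stringr::str_match(samples, "^(.*)_([^_]+)$")
    if (any(is.na(m[, 1]))) {
      abort("sample labels are not of the form <condition>_<replicate>; supply `design`.")
    }
    design <- tibble(sample = samples, condition = m[, 2], replicate = m[, 3])
  }
  expression_matrix(num, design, feature_class, conditions = conditions)
}

#' @param expr A `cerna_expr` tibble.
#' @rdname read_expression
#' @export
write_expression <- function(expr, path) {
  wide <- expr |>
    mutate(sample = paste(.data$condition, .data$replicate, sep = "_")) |>
    select("feature_id", "sample", "abundance") |>
    pivot_wider(names_from = "sample", values_from = "abundance")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Period order of an expression table
#' @param expr A `cerna_expr` tibble.
#' @return Character vector of condition labels in period order.
#' @export
expr_conditions <- function(expr) levels(expr$condition)

# features x samples matrix, samples ordered by (condition, replicate)
expr_wide <- function(expr) {
  wide <- expr |>
    arrange(.data$condition, .data$replicate, .data$feature_id) |>
    mutate(sample = paste(.data$condition, .data$replicate, sep = "_")) |>
    select("feature_id", "sample", "abundance") |>
    pivot_wider(names_from = "sample", values_from = "abundance")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$feature_id
  mat
}

# per-condition arithmetic means on the linear scale
expr_condition_means <- function(expr) {
  expr |>
    group_by(.data$feature_id, .data$condition) |>
    summarise(mean_abundance = mean(.data$abundance), .groups = "drop")
}
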