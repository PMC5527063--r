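#' Log2 fold change with pseudocount
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`: the change of
#' condition `b` relative to condition `a`. Antisymmetric under swapping the
#' two conditions; zero when both means are zero. Vectorised.
#'
#' @param mean_a,mean_b Non-negative condition means (linear scale).
#' @param pseudocount Positive stabiliser added to both means.
#' @return Log2 fold change(s).
#' @export
#' @examples
#' log2_fold_change(5, 10, 1) # log2(11/6)
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  if (any(mean_a < 0) || any(mean_b < 0)) {
    abort("condition means must be non-negative.")
  }
  if (any(pseudocount <= 0)) abort("pseudocount must be positive.")
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

# vectorised Welch two-sample t-test on rows of two matrices (log2 scale),
# with a per-feature variance floor so zero-variance features are testable
welch_p <- function(xa, xb, var_floor = 1e-8) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- pmax(rowSums((xa - ma)^2) / (na - 1), var_floor)
  vb <- pmax(rowSums((xb - mb)^2) / (nb - 1), var_floor)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(abs(tstat), df, lower.tail = FALSE)
}

#' Differential-expression test between two conditions
#'
#' Tests every feature of one RNA class between two periods with a Welch
#' two-sample location test on `log2(abundance + pseudocount)` (a documented
#' stand-in for the external count-based tools whose outputs can be injected
#' via `pvalues`). BH-adjusted q-values are computed over all features in
#' the comparison. The significance call follows the class-specific
#' thresholds: miRNAs need raw `p < 0.05`, `|fold change| > 2` and a
#' miRDeep2 score of at least 1 (unscored records pass the score gate);
#' mRNAs and lncRNAs need `q < 0.05`.
#'
#' @param expr A `cerna_expr` tibble (one RNA class).
#' @param comparison Character vector `c(condition_a, condition_b)`; fold
#'   changes are `b` relative to `a`.
#' @param config A [cerna_config()].
#' @param scores Optional named numeric vector of miRDeep2 scores keyed by
#'   feature id (miRNA class only).
#' @param pvalues Optional tibble (`feature_id`, `p`) of externally computed
#'   p-values that replace the built-in test for this comparison.
#'
#' @return A tibble with one row per feature: `feature_id`, `feature_class`,
#'   `condition_a`, `condition_b`, `comparison`, `mean_a`, `mean_b`,
#'   `log2_fc`, `p`, `q`, `is_de`.
#' @export
de_test <- function(expr, comparison, config = cerna_config(),
                    scores = NULL, pvalues = NULL) {
  stopifnot(length(comparison) == 2)
  conds <- expr_conditions(expr)
  if (!all(comparison %in% conds)) {
    abort(sprintf("unknown condition(s): %s",
                  paste(setdiff(comparison, conds), collapse = ", ")))
  }
  sub <- expr |> filter(.data$condition %in% comparison)
  reps <- sub |>
    distinct(.data$condition, .data$replicate) |>
    count(.data$condition)
  short <- comparison[!comparison %in% reps$condition[reps$n >= 2]]
  if (length(short) > 0) {
    abort(sprintf("condition '%s' has fewer than 2 replicates.", short[1]))
  }
  feature_class <- sub$feature_class[1]
  pc <- config$pseudocount

  wide_of <- function(cond) {
    m <- expr_wide(sub |> filter(.data$condition == cond))
    m[sort(rownames(m)), , drop = FALSE]
  }
  xa <- wide_of(comparison[1])
  xb <- wide_of(comparison[2])
  stopifnot(identical(rownames(xa), rownames(xb)))
  fids <- rownames(xa)

  res <- tibble(
    feature_id = fids,
    feature_class = feature_class,
    condition_a = comparison[1],
    condition_b = comparison[2],
    comparison = paste0(comparison[2], "_vs_", comparison[1]),
    mean_a = unname(rowMeans(xa)),
    mean_b = unname(rowMeans(xb)),
    log2_fc = unname(log2_fold_change(rowMeans(xa), rowMeans(xb), pc)),
    p = unname(welch_p(log2(xa + pc), log2(xb + pc)))
  )
  if (!is.null(pvalues)) {
    idx <- match(res$feature_id, pvalues$feature_id)
    res$p <- ifelse(is.na(idx), res$p, pvalues$p[idx])
  }
  res$q <- p.adjust(res$p, method = "BH")
  res$is_de <- de_call(res, feature_class, config, scores)
  res
}

de_call <- function(res, feature_class, config, scores) {
  if (feature_class == "miRNA") {
    sc <- if (is.null(scores)) rep(NA_real_, nrow(res)) else
      unname(scores[res$feature_id])
    score_ok <- is.na(sc) | sc >= config$mirna_min_score
    res$p < config$mirna_p &
      abs(res$log2_fc) > log2(config$mirna_min_abs_fc) &
      score_ok
  } else {
    res$q < config$gene_q
  }
}

#' Differential expression over all pairwise period comparisons
#'
#' Runs [de_test()] for every ordered pair of periods (later vs earlier)
#' and binds the results. A feature is "differentially expressed between at
#' least two of the periods" if it is called in any comparison.
#'
#' @inheritParams de_test
#' @return A tibble of per-comparison results (class `cerna_de`).
#' @export
run_de_analysis <- function(expr, config = cerna_config(), scores = NULL,
                            pvalues = NULL) {
  conds <- expr_conditions(expr)
  pairs_idx <- utils::combn(length(conds), 2)
  out <- map(seq_len(ncol(pairs_idx)), function(j) {
    cmp <- conds[pairs_idx[, j]]
    pv <- if (!is.null(pvalues)) {
      pvalues |>
        filter(.data$comparison == paste0(cmp[2], "_vs_", cmp[1]))
    } else NULL
    de_test(expr, cmp, config, scores = scores, pvalues = pv)
  }) |> bind_rows()
  class(out) <- c("cerna_de", class(out))
  out
}

#' Classify expression trends across ordered periods
#'
#' For every feature, compares consecutive condition means on the log2
#' scale and assigns `up`, `down` or `flat` per step; a step is `flat` when
#' `|log2 ratio| <= trend_epsilon`. The result has `n_conditions - 1`
#' direction entries per feature, joined into a `pattern` string such as
#' `"up/down"`.
#'
#' @param expr A `cerna_expr` tibble.
#' @param config A [cerna_config()]; uses `trend_epsilon` and `pseudocount`.
#' @return A tibble: `feature_id`, `feature_class`, `directions`
#'   (list-column of character vectors), `pattern`.
#' @export
classify_trends <- function(expr, config = cerna_config()) {
  pc <- config$pseudocount
  eps <- config$trend_epsilon
  means <- expr_condition_means(expr) |>
    arrange(.data$feature_id, .data$condition)
  cls <- expr |> distinct(.data$feature_id, .data$feature_class)
  means |>
    group_by(.data$feature_id) |>
    summarise(directions = list({
      m <- .data$mean_abundance
      d <- log2((m[-1] + pc) / (m[-length(m)] + pc))
      ifelse(abs(d) <= eps, "flat", ifelse(d > 0, "up", "down"))
    }), .groups = "drop") |>
    mutate(pattern = map_chr(.data$directions, paste, collapse = "/")) |>
    left_join(cls, by = "feature_id") |>
    select("feature_id", "feature_class", "directions", "pattern")
}

#' Trend of a single feature
#'
#' @inheritParams classify_trends
#' @param feature_id Feature to look up.
#' @return A one-row trend tibble.
#' @export
classify_trend <- function(expr, feature_id, config = cerna_config()) {
  if (!feature_id %in% expr$feature_id) {
    abort(sprintf("unknown feature '%s'.", feature_id))
  }
  classify_trends(expr |> filter(.data$feature_id == !!feature_id), config)
}

flip_direction <- function(dirs) {
  ifelse(dirs == "up", "down", ifelse(dirs == "down", "up", "flat"))
}
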