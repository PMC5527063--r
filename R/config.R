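#' Analysis configuration
#'
#' Bundles every threshold the pipeline applies, with defaults matching the
#' study design the package implements: miRNAs are called differentially
#' expressed at raw `p < 0.05` with `|fold change| > 2` and a miRDeep2 score
#' of at least 1; mRNAs and lncRNAs at BH-adjusted `q < 0.05`; lncRNA cis
#' targets are coding genes within a symmetric 100-kb genomic window; trans
#' targets require `|Pearson r| > 0.95` (strict); candidate ceRNA pairs are
#' retained at hypergeometric `p < 0.05`.
#'
#' @param mirna_p Raw p-value threshold for miRNA differential expression.
#' @param mirna_min_abs_fc Minimum absolute (linear) fold change for miRNAs;
#'   the gate is strict (`|FC| > 2` with the default).
#' @param mirna_min_score Minimum miRDeep2 score for novel miRNAs; records
#'   without a score (known miRNAs) pass this gate.
#' @param gene_q BH-adjusted q-value threshold for mRNA/lncRNA differential
#'   expression.
#' @param cis_window_bp Symmetric genomic window (bp) for cis target search;
#'   the boundary is inclusive (a gap of exactly `cis_window_bp` qualifies).
#' @param trans_min_abs_r Minimum absolute Pearson correlation for trans
#'   targets; strict (`|r|` equal to the threshold is excluded).
#' @param cerna_alpha Significance level for the shared-miRNA hypergeometric
#'   test on candidate ceRNA pairs.
#' @param cerna_gate Which statistic the ceRNA retention gate uses: `"p"`
#'   (raw hypergeometric p, the default) or `"q"` (BH-adjusted).
#' @param rescore How a pair is re-scored after a same-trend miRNA is dropped
#'   from its shared set: `"c_only"` (default) shrinks only the shared count
#'   `c`, keeping the degrees `K` and `n` (the dropped miRNA still targets
#'   both members); `"full"` also decrements `K` and `n`.
#' @param lnc_min_len Minimum mature transcript length (sum of exon lengths,
#'   bp) for lncRNA candidates; inclusive.
#' @param lnc_min_exons Minimum exon count for lncRNA candidates; inclusive.
#' @param lnc_min_cov Minimum read coverage in at least one sample; inclusive.
#' @param coding_filter Consensus rule for the coding-potential step of the
#'   lncRNA filter: `"all"` (default) removes transcripts called coding by
#'   all four classifiers; `"any"` removes transcripts called coding by any.
#' @param trend_epsilon Half-width (log2 units) of the "flat" band when
#'   classifying expression trends between consecutive periods.
#' @param pseudocount Pseudocount added to abundances before log2 transforms
#'   and fold-change ratios.
#' @param n_total_mirnas Size `N` of the miRNA universe for the
#'   hypergeometric test. `NULL` (default) resolves to the number of distinct
#'   miRNAs in the supplied target table.
#' @param rng_seed Integer seed for any stochastic step.
#'
#' @return A list of class `cerna_config`.
#' @export
#' @examples
#' cfg <- cerna_config(trend_epsilon = 0.1)
#' cfg$trend_epsilon
cerna_config <- function(mirna_p = 0.05,
                         mirna_min_abs_fc = 2,
                         mirna_min_score = 1,
                         gene_q = 0.05,
                         cis_window_bp = 100000,
                         trans_min_abs_r = 0.95,
                         cerna_alpha = 0.05,
                         cerna_gate = c("p", "q"),
                         rescore = c("c_only", "full"),
                         lnc_min_len = 200,
                         lnc_min_exons = 2,
                         lnc_min_cov = 3,
                         coding_filter = c("all", "any"),
                         trend_epsilon = 0.25,
                         pseudocount = 1,
                         n_total_mirnas = NULL,
                         rng_seed = 1L) {
  cfg <- list(
    mirna_p = mirna_p,
    mirna_min_abs_fc = mirna_min_abs_fc,
    mirna_min_score = mirna_min_score,
    gene_q = gene_q,
    cis_window_bp = cis_window_bp,
    trans_min_abs_r = trans_min_abs_r,
    cerna_alpha = cerna_alpha,
    cerna_gate = match.arg(cerna_gate),
    rescore = match.arg(rescore),
    lnc_min_len = lnc_min_len,
    lnc_min_exons = lnc_min_exons,
    lnc_min_cov = lnc_min_cov,
    coding_filter = match.arg(coding_filter),
    trend_epsilon = trend_epsilon,
    pseudocount = pseudocount,
    n_total_mirnas = n_total_mirnas,
    rng_seed = as.integer(rng_seed)
  )
  validate_cerna_config(cfg)
  structure(cfg, class = "cerna_config")
}

validate_cerna_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$mirna_p), cfg$mirna_p > 0, cfg$mirna_p <= 1,
    cfg$mirna_min_abs_fc >= 1,
    cfg$mirna_min_score >= 0,
    cfg$gene_q > 0, cfg$gene_q <= 1,
    cfg$cis_window_bp >= 0,
    cfg$trans_min_abs_r >= 0, cfg$trans_min_abs_r <= 1,
    cfg$cerna_alpha > 0, cfg$cerna_alpha <= 1,
    cfg$lnc_min_len >= 0, cfg$lnc_min_exons >= 1, cfg$lnc_min_cov >= 0,
    cfg$trend_epsilon >= 0,
    cfg$pseudocount > 0,
    is.null(cfg$n_total_mirnas) ||
      (is.numeric(cfg$n_total_mirnas) && cfg$n_total_mirnas >= 1)
  )
  invisible(cfg)
}

#' @export
print.cerna_config <- function(x, ...) {
  cat("<cerna_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm, if (is.null(val)) "NULL" else format(val)))
  }
  invisible(x)
}

#' Read or write a configuration as YAML
#'
#' The on-disk form round-trips losslessly: `read_config(write_config(cfg))`
#' reproduces every field, including an unset miRNA universe size.
#'
#' @param config A [cerna_config()] object.
#' @param path File path for the YAML document.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `cerna_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cerna_config"))
  out <- unclass(config)
  out$n_total_mirnas <- out$n_total_mirnas %||% NA
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$n_total_mirnas) || isTRUE(is.na(raw$n_total_mirnas))) {
    raw$n_total_mirnas <- NULL
  }
  do.call(cerna_config, raw)
}
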