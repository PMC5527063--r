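#' Run the full ceRNA inference pipeline
#'
#' Orchestrates the analysis end to end in a fixed stage order — lncRNA
#' candidate filtering, differential expression for the three RNA classes,
#' trend classification, candidate ceRNA pair scoring, trend pruning,
#' network summary — and writes deterministic artifacts to `output_dir`:
#' `pairs.tsv` (final network, flat), `candidates.tsv` (all scored
#' candidates), `network.graphml`, `summary.tsv`, `de_results.tsv`,
#' `lncrna_filter_log.tsv` and `manifest.json`. Re-running with the same
#' inputs and configuration reproduces the pair table byte-for-byte. An
#' empty target table yields a valid empty network with a warning.
#'
#' Inputs are taken either from an in-memory simulated dataset (`sim`) or
#' from files produced by the package's writers (the escape hatch for real
#' data: externally computed target tables or DE p-values can be spliced
#' in at the matching stage).
#'
#' @param sim A `cerna_sim` object from [simulate_cerna_dataset()], or
#'   `NULL` when file inputs are given.
#' @param inputs Optional named list of file paths: `expr_mrna`,
#'   `expr_lncrna`, `expr_mirna` (TSV expression matrices), `targets`
#'   (target table TSV), optionally `gtf` (annotation) and `coding_calls`.
#' @param config A [cerna_config()].
#' @param output_dir Directory for artifacts; created if missing. `NULL`
#'   skips writing.
#' @param pvalues Optional externally computed p-values
#'   (`feature_id`, `comparison`, `p`) forwarded to the DE stage.
#' @return A list of class `cerna_run`: `filter`, `de`, `trends`,
#'   `network` (a `cerna_network`), `manifest`.
#' @export
run_cerna_pipeline <- function(sim = NULL, inputs = NULL,
                               config = cerna_config(),
                               output_dir = NULL, pvalues = NULL) {
  if (is.null(sim) && is.null(inputs)) {
    abort("supply either `sim` or `inputs`.")
  }
  if (is.null(sim)) {
    need <- c("expr_mrna", "expr_lncrna", "expr_mirna", "targets")
    missing_in <- setdiff(need, names(inputs))
    if (length(missing_in) > 0) {
      abort(sprintf("missing required input(s): %s",
                    paste(missing_in, collapse = ", ")))
    }
    for (f in unlist(inputs)) {
      if (!file.exists(f)) abort(sprintf("input file not found: '%s'", f))
    }
    expr <- list(
      mRNA = read_expression(inputs$expr_mrna, "mRNA"),
      lncRNA = read_expression(inputs$expr_lncrna, "lncRNA"),
      miRNA = read_expression(inputs$expr_mirna, "miRNA")
    )
    edges <- read_target_table(inputs$targets)
    records <- if (!is.null(inputs$gtf)) read_annotation(inputs$gtf)
    if (!is.null(records) && !is.null(inputs$coding_calls)) {
      records <- records |>
        left_join(read_coding_calls(inputs$coding_calls),
                  by = "transcript_id")
    }
  } else {
    expr <- sim$expr
    edges <- sim$edges
    records <- sim$records
  }

  # stage 1: lncRNA candidate filter (when annotation is available)
  filt <- NULL
  if (!is.null(records) && "biotype" %in% names(records)) {
    lnc_records <- records |>
      filter(.data$transcript_id %in% unique(expr$lncRNA$feature_id))
    filt <- filter_lncrna_candidates(lnc_records, config)
    keep_ids <- filt$kept$transcript_id
    expr$lncRNA <- expr$lncRNA |>
      filter(.data$feature_id %in% keep_ids)
  }

  # stage 2: differential expression per class
  scores <- NULL
  if (!is.null(records) && "mirdeep2_score" %in% names(records)) {
    mir_rec <- records |> filter(.data$transcript_id %in%
                                   unique(expr$miRNA$feature_id))
    scores <- setNames(mir_rec$mirdeep2_score, mir_rec$transcript_id)
  }
  de <- bind_rows(
    run_de_analysis(expr$mRNA, config, pvalues = pvalues),
    run_de_analysis(expr$lncRNA, config, pvalues = pvalues),
    run_de_analysis(expr$miRNA, config, scores = scores,
                    pvalues = pvalues)
  )

  # stage 3: trend profiles across the ordered periods
  trends <- bind_rows(
    classify_trends(expr$mRNA, config),
    classify_trends(expr$lncRNA, config),
    classify_trends(expr$miRNA, config)
  )

  # stage 4-5: candidate scoring and trend pruning
  if (nrow(edges) == 0) {
    warn("empty target table: the resulting network is empty.")
  }
  network <- build_cerna_network(edges, de, trends, config)

  manifest <- list(
    tool = "cernet",
    version = as.character(packageVersion("cernet")),
    config = unclass(config),
    n_features = as.list(map_int(expr, ~ n_distinct(.x$feature_id))),
    n_target_edges = nrow(edges),
    n_de_calls = de |> filter(.data$is_de) |>
      distinct(.data$feature_id, .data$feature_class) |> nrow(),
    n_candidate_pairs = nrow(network$candidates),
    n_significant_pairs = sum(network$candidates$significant),
    n_final_pairs = nrow(network$network),
    rng_seed = config$rng_seed
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(output_dir, f)
    write_network(network$network, p("pairs.tsv"), "tsv")
    write_network(network$network, p("network.graphml"), "graphml")
    readr::write_tsv(flatten_pairs(network$candidates),
                     p("candidates.tsv"), progress = FALSE)
    readr::write_tsv(network$summary, p("summary.tsv"), progress = FALSE)
    readr::write_tsv(de, p("de_results.tsv"), progress = FALSE)
    if (!is.null(filt)) {
      readr::write_tsv(filt$log, p("lncrna_filter_log.tsv"),
                       progress = FALSE)
    }
    manifest$checksums <- as.list(tools::md5sum(
      c(p("pairs.tsv"), p("candidates.tsv"), p("summary.tsv"))
    ))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  structure(
    list(filter = filt, de = de, trends = trends, network = network,
         manifest = manifest),
    class = "cerna_run"
  )
}

#' @export
print.cerna_run <- function(x, ...) {
  cat("<cerna_run>\n")
  cat(sprintf("  DE calls: %d | candidate pairs: %d | final pairs: %d\n",
              x$manifest$n_de_calls, x$manifest$n_candidate_pairs,
              x$manifest$n_final_pairs))
  invisible(x)
}
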