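#' Read a miRNA target table
#'
#' The target table is the directed edge set miRNA -> target feeding the
#' ceRNA stage, as a TSV with columns `mirna`, `target`, `class`
#' (`mRNA` or `lncRNA`) and optionally `score`. Exact duplicate
#' (miRNA, target) pairs are collapsed with a warning (the first score is
#' kept); an unknown class token or a target listed under two classes is an
#' error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `mirna_id`, `target_id`, `target_class`,
#'   `score`.
#' @export
read_target_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_guess()
  ), progress = FALSE)
  if (!all(c("mirna", "target", "class") %in% names(raw))) {
    abort(sprintf("'%s': expected columns mirna, target, class.", path))
  }
  if (!"score" %in% names(raw)) raw$score <- NA_real_
  raw <- raw |>
    mutate(across(c("mirna", "target", "class"), as.character),
           score = as.numeric(.data$score))
  edges <- tibble(
    mirna_id = raw$mirna,
    target_id = raw$target,
    target_class = raw$class,
    score = raw$score
  )
  validate_target_table(edges, source = path)
}

validate_target_table <- function(edges, source = "target table") {
  bad <- setdiff(unique(edges$target_class), c("mRNA", "lncRNA"))
  if (length(bad) > 0) {
    abort(sprintf("%s: unknown target class token '%s'.", source, bad[1]))
  }
  ndup <- sum(duplicated(edges[c("mirna_id", "target_id")]))
  if (ndup > 0) {
    warn(sprintf("%s: collapsed %d duplicate edge(s).", source, ndup))
    edges <- edges |>
      distinct(.data$mirna_id, .data$target_id, .keep_all = TRUE)
  }
  ambig <- edges |>
    distinct(.data$target_id, .data$target_class) |>
    count(.data$target_id) |>
    filter(.data$n > 1)
  if (nrow(ambig) > 0) {
    abort(sprintf("%s: target '%s' appears under two classes.",
                  source, ambig$target_id[1]))
  }
  edges
}

#' @param edges A target-table tibble.
#' @param path Output path.
#' @rdname read_target_table
#' @export
write_target_table <- function(edges, path) {
  edges |>
    select(mirna = "mirna_id", target = "target_id",
           class = "target_class", "score") |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Export a ceRNA network
#'
#' Writes finalized ceRNA pairs either as a flat TSV (shared miRNA ids
#' semicolon-joined, deterministic row order) or as a tripartite GraphML
#' graph in which every node carries a `type` attribute (`lncRNA`, `miRNA`
#' or `mRNA`), lncRNA--mRNA edges carry the hypergeometric `p` and BH `q`,
#' and miRNA--member edges represent the shared targeting relations.
#' An empty pair list produces a valid empty file.
#'
#' @param pairs Tibble of ceRNA pairs as produced by [build_cerna_network()]
#'   (or its `tidy()` method).
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(pairs, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  pairs <- flatten_pairs(pairs)
  if (format == "tsv") {
    readr::write_tsv(pairs, path, progress = FALSE)
  } else {
    g <- pairs_to_igraph(pairs)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

flatten_pairs <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(tibble(
      lncrna_id = character(), mrna_id = character(),
      comparison = character(), c = integer(), K = integer(),
      n = integer(), N = integer(), p = double(), q = double(),
      shared_mirnas = character(), trend_consistent = logical()
    ))
  }
  out <- pairs
  if (is.list(out$shared_mirnas)) {
    out$shared_mirnas <- map_chr(out$shared_mirnas,
                                 ~ paste(sort(.x), collapse = ";"))
  }
  if (!"trend_consistent" %in% names(out)) out$trend_consistent <- NA
  out |>
    select("lncrna_id", "mrna_id", "comparison", "c", "K", "n", "N",
           "p", "q", "shared_mirnas", "trend_consistent") |>
    arrange(.data$comparison, .data$lncrna_id, .data$mrna_id)
}

pairs_to_igraph <- function(flat) {
  if (nrow(flat) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  shared <- strsplit(flat$shared_mirnas, ";", fixed = TRUE)
  mirnas <- sort(unique(unlist(shared)))
  nodes <- tibble(
    name = c(sort(unique(flat$lncrna_id)), mirnas,
             sort(unique(flat$mrna_id))),
    type = c(rep("lncRNA", length(unique(flat$lncrna_id))),
             rep("miRNA", length(mirnas)),
             rep("mRNA", length(unique(flat$mrna_id))))
  )
  cerna_edges <- tibble(
    from = flat$lncrna_id, to = flat$mrna_id, kind = "cerna",
    p = flat$p, q = flat$q, comparison = flat$comparison
  )
  tgt <- tibble(
    from = c(unlist(shared), unlist(shared)),
    to = c(rep(flat$lncrna_id, lengths(shared)),
           rep(flat$mrna_id, lengths(shared))),
    kind = "targets", p = NA_real_, q = NA_real_,
    comparison = NA_character_
  ) |> distinct(.data$from, .data$to, .keep_all = TRUE)
  edges <- bind_rows(cerna_edges, tgt)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Read a GraphML ceRNA network
#'
#' @param path Path to a GraphML file written by [write_network()].
#' @return An igraph graph.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings used for miRNA mature sequences and target
#' (3'UTR / lncRNA) sequences.
#'
#' @param path FASTA file path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
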