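#' Cis target genes of lncRNAs
#'
#' A coding gene is a cis target of a lncRNA when both lie on the same
#' chromosome and the coordinate gap between the two intervals is at most
#' `window_bp` (inclusive; overlapping intervals have gap 0). The search is
#' strand-agnostic: the window is symmetric upstream and downstream in
#' reference orientation. The reported distance is signed by relative
#' genomic position: negative when the gene lies upstream of (before) the
#' lncRNA, positive when downstream, 0 on overlap.
#'
#' @param lncrnas,genes Tibbles with columns `transcript_id` (or `id`),
#'   `chromosome`, `start`, `end` (1-based inclusive).
#' @param window_bp Window half-width in bp (default 100,000).
#' @return A tibble `lncrna_id`, `gene_id`, `distance`, sorted.
#' @export
cis_targets <- function(lncrnas, genes, window_bp = 100000) {
  norm <- function(df, idcol) {
    if (!"transcript_id" %in% names(df) && "id" %in% names(df)) {
      df <- rename(df, transcript_id = "id")
    }
    df <- df |> select("transcript_id", "chromosome", "start", "end")
    names(df)[1] <- idcol
    df
  }
  l <- norm(lncrnas, "lncrna_id")
  g <- norm(genes, "gene_id")
  if (nrow(l) == 0 || nrow(g) == 0) {
    return(tibble(lncrna_id = character(0), gene_id = character(0),
                  distance = double(0)))
  }
  inner_join(l, g, by = "chromosome", suffix = c("_l", "_g"),
             relationship = "many-to-many") |>
    mutate(
      gap = pmax(0, .data$start_l - .data$end_g,
                 .data$start_g - .data$end_l),
      distance = dplyr::case_when(
        .data$end_g < .data$start_l ~ .data$end_g - .data$start_l,
        .data$start_g > .data$end_l ~ .data$start_g - .data$end_l,
        TRUE ~ 0
      )
    ) |>
    filter(.data$gap <= window_bp) |>
    select("lncrna_id", "gene_id", "distance") |>
    arrange(.data$lncrna_id, .data$gene_id)
}

#' Trans target genes of lncRNAs by expression correlation
#'
#' Computes the Pearson correlation between every lncRNA and every gene
#' across all samples, by default on `log2(abundance + pseudocount)`, and
#' keeps pairs with `|r|` strictly greater than `min_abs_r`. Constant
#' (zero-variance) profiles have undefined correlation and yield no edge.
#' Both expression tables must share an identical sample design.
#'
#' @param expr_lncrna,expr_genes `cerna_expr` tibbles over the same samples.
#' @param min_abs_r Strict absolute-correlation threshold (default 0.95).
#' @param log_scale Correlate on log2(x + pseudocount) (default) or on the
#'   linear scale.
#' @param pseudocount Pseudocount for the log transform.
#' @return A tibble `lncrna_id`, `gene_id`, `r`, sorted.
#' @export
trans_targets <- function(expr_lncrna, expr_genes, min_abs_r = 0.95,
                          log_scale = TRUE, pseudocount = 1) {
  design <- function(e) e |>
    distinct(.data$condition, .data$replicate) |>
    arrange(.data$condition, .data$replicate)
  if (!identical(design(expr_lncrna), design(expr_genes))) {
    abort("sample designs of the two expression tables differ.")
  }
  ml <- expr_wide(expr_lncrna)
  mg <- expr_wide(expr_genes)
  if (ncol(ml) < 3) abort("at least 3 samples are required.")
  if (log_scale) {
    ml <- log2(ml + pseudocount)
    mg <- log2(mg + pseudocount)
  }
  keep_var <- function(m) m[apply(m, 1, function(x) var(x) > 0), ,
                            drop = FALSE]
  ml <- keep_var(ml)
  mg <- keep_var(mg)
  if (nrow(ml) == 0 || nrow(mg) == 0) {
    return(tibble(lncrna_id = character(0), gene_id = character(0),
                  r = double(0)))
  }
  rmat <- cor(t(ml), t(mg))
  hits <- which(abs(rmat) > min_abs_r, arr.ind = TRUE)
  tibble(
    lncrna_id = rownames(rmat)[hits[, 1]],
    gene_id = colnames(rmat)[hits[, 2]],
    r = rmat[hits]
  ) |>
    arrange(.data$lncrna_id, .data$gene_id)
}

#' Scan target sequences for miRNA seed sites
#'
#' Finds miRNA response elements (MREs) as exact matches of the reverse
#' complement of the miRNA seed (positions 2-8 of the mature sequence) in
#' each target sequence — a deterministic seed-match criterion with no G:U
#' wobble and no free-energy term. Users with externally predicted target
#' tables can bypass the scanner entirely via [read_target_table()].
#' RNA and DNA alphabets are accepted (U and T are equivalent); all
#' reported positions are 1-based, and hits are ordered by (target,
#' position, miRNA).
#'
#' @param mirna_seqs Named character vector of mature miRNA sequences
#'   (each at least 8 nt).
#' @param target_seqs Named character vector of target sequences.
#' @param target_class Optional single class label (`"mRNA"` or
#'   `"lncRNA"`) applied to all targets in the returned edge table.
#' @return A list with `edges` (tibble `mirna_id`, `target_id`,
#'   `target_class`, `n_sites`) and `hits` (tibble `mirna_id`, `target_id`,
#'   `site_start`, `site_type = "7mer-seed"`).
#' @export
scan_mre <- function(mirna_seqs, target_seqs, target_class = NA_character_) {
  check_alphabet <- function(x, what) {
    bad <- grepl("[^ACGUTacgut]", x)
    if (any(bad)) {
      abort(sprintf("%s '%s' contains non-ACGU/ACGT characters.",
                    what, names(x)[bad][1] %||% "?"))
    }
  }
  check_alphabet(mirna_seqs, "miRNA sequence")
  check_alphabet(target_seqs, "target sequence")
  mir <- toupper(chartr("Uu", "Tt", mirna_seqs))
  tgt <- toupper(chartr("Uu", "Tt", target_seqs))
  if (any(nchar(mir) < 8)) {
    abort(sprintf("miRNA '%s' is shorter than 8 nt.",
                  names(mir)[nchar(mir) < 8][1]))
  }
  sites <- revcomp_dna(substr(mir, 2, 8))
  tgt_set <- Biostrings::DNAStringSet(tgt)
  hits <- map(seq_along(sites), function(i) {
    m <- Biostrings::vmatchPattern(sites[i], tgt_set)
    st <- BiocGenerics::start(m)
    found <- which(lengths(st) > 0)
    if (length(found) == 0) return(NULL)
    tibble(
      mirna_id = names(mir)[i],
      target_id = rep(names(tgt)[found], lengths(st)[found]),
      site_start = unname(unlist(st[found])),
      site_type = "7mer-seed"
    )
  }) |> bind_rows()
  if (nrow(hits) == 0) {
    hits <- tibble(mirna_id = character(0), target_id = character(0),
                   site_start = integer(0), site_type = character(0))
  }
  hits <- hits |>
    arrange(.data$target_id, .data$site_start, .data$mirna_id)
  edges <- hits |>
    count(.data$mirna_id, .data$target_id, name = "n_sites") |>
    mutate(target_class = target_class, .before = "n_sites") |>
    arrange(.data$mirna_id, .data$target_id)
  list(edges = edges, hits = hits)
}
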