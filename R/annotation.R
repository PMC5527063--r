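#' Read transcript models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (attributes `gene_id`/`transcript_id`) and
#' summarises exon features into one record per transcript. Coordinates are
#' 1-based inclusive throughout the package, matching GTF. Transcript length
#' is the mature length, i.e. the sum of exon lengths
#' (`end - start + 1` per exon), the convention coding-potential classifiers
#' use; the genomic span is reported separately as `start`/`end`.
#'
#' @param path Path to a GTF file whose exon lines carry `transcript_id`.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chromosome`, `strand`, `start`, `end`, `exon_count`, `length`.
#' @export
read_annotation <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) {
      abort(sprintf("'%s': malformed GTF (%s)", path, conditionMessage(e)))
    }
  )
  df <- as.data.frame(gr)
  if (!"type" %in% names(df) || !"transcript_id" %in% names(df)) {
    abort(sprintf("'%s': GTF lacks type/transcript_id attributes.", path))
  }
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) abort(sprintf("'%s': no exon features found.", path))
  if (any(ex$end < ex$start)) {
    bad <- ex$transcript_id[ex$end < ex$start][1]
    abort(sprintf("'%s': malformed exon (end < start) in transcript '%s'.",
                  path, bad))
  }
  ex |>
    as_tibble() |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = dplyr::first(.data$gene_id),
      chromosome = as.character(dplyr::first(.data$seqnames)),
      strand = as.character(dplyr::first(.data$strand)),
      exon_count = dplyr::n(),
      length = sum(.data$end - .data$start + 1L),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    ) |>
    select("transcript_id", "gene_id", "chromosome", "strand",
           "start", "end", "exon_count", "length") |>
    arrange(.data$transcript_id)
}

#' Write exon models to a GTF file
#'
#' @param exons Tibble with one row per exon: `transcript_id`, `gene_id`,
#'   `chromosome`, `strand`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(exons, path) {
  stopifnot(all(c("transcript_id", "gene_id", "chromosome", "strand",
                  "start", "end") %in% names(exons)))
  if (any(exons$end < exons$start)) {
    abort("exon with end < start.")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chromosome,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    strand = exons$strand
  )
  gr$type <- "exon"
  gr$source <- "cernet"
  gr$gene_id <- exons$gene_id
  gr$transcript_id <- exons$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read coding-potential calls
#'
#' Reads the four-classifier consensus table consumed by the lncRNA filter:
#' columns `transcript_id`, `cnci`, `cpc`, `pfam`, `phylocsf` with 0/1
#' values (1 = called coding by that tool).
#'
#' @param path Path to the TSV.
#' @return Tibble with a logical column per classifier.
#' @export
read_coding_calls <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ciiii", progress = FALSE)
  need <- c("transcript_id", "cnci", "cpc", "pfam", "phylocsf")
  if (!all(need %in% names(raw))) {
    abort(sprintf("'%s': expected columns %s.", path,
                  paste(need, collapse = ", ")))
  }
  vals <- unlist(raw[c("cnci", "cpc", "pfam", "phylocsf")])
  if (any(!vals %in% c(0L, 1L))) {
    abort(sprintf("'%s': coding calls must be 0 or 1.", path))
  }
  raw |>
    mutate(across(c("cnci", "cpc", "pfam", "phylocsf"), as.logical))
}
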