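# seed handling: the miRNA seed is positions 2-8 of the mature sequence;
# a target site is the reverse complement of that 7-mer (DNA alphabet)

DNA_BASES <- c("A", "C", "G", "T")

revcomp_dna <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

int_to_kmer <- function(i, k = 7) {
  # i in 0 .. 4^k - 1, base-4 expansion to a k-mer
  out <- character(k)
  for (p in seq_len(k)) {
    out[p] <- DNA_BASES[(i %% 4) + 1]
    i <- i %/% 4
  }
  paste(out, collapse = "")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate miRNA and target sequences with planted seed sites
#'
#' Produces a pair of sequence sets consistent with a target edge table:
#' mature miRNA sequences (RNA alphabet) whose seeds (positions 2-8) are
#' distinct across miRNAs, and target sequences (DNA alphabet) such that for
#' every edge the target contains at least one exact match to the reverse
#' complement of the miRNA seed, while every non-edge (miRNA, target)
#' combination has no such site (offending 7-mers are rejection-sampled
#' away). [scan_mre()] on the output therefore recovers exactly the input
#' edge set.
#'
#' @param spec A [simulation_spec()]; `target_length`, `mirna_length` and
#'   `rng_seed` are used.
#' @param records Annotation tibble with `transcript_id` and `feature_class`
#'   (as produced by [simulate_cerna_dataset()]); determines which ids get
#'   miRNA vs target sequences.
#' @param edges Target table tibble (`mirna_id`, `target_id`).
#' @return A list with named character vectors `mirna` (RNA) and `targets`
#'   (DNA).
#' @export
simulate_sequences <- function(spec, records, edges) {
  set.seed(spec$rng_seed, kind = "Mersenne-Twister")
  mirna_ids <- records$transcript_id[records$feature_class == "miRNA"]
  target_ids <- records$transcript_id[records$feature_class != "miRNA"]
  n_mir <- length(mirna_ids)
  if (n_mir > 4^7) abort("more miRNAs than distinct 7-mer seeds.")
  if (!all(edges$mirna_id %in% mirna_ids) ||
      !all(edges$target_id %in% target_ids)) {
    abort("edge table references ids absent from the annotation.")
  }

  seeds <- vapply(sample.int(4^7, n_mir) - 1L, int_to_kmer, character(1))
  sites <- revcomp_dna(seeds) # site string expected on the target
  names(seeds) <- names(sites) <- mirna_ids

  mirna_seqs <- vapply(seq_len(n_mir), function(i) {
    rest <- spec$mirna_length - 8L
    s <- paste0(random_dna(1), seeds[i],
                if (rest > 0) random_dna(rest) else "")
    chartr("T", "U", s)
  }, character(1))
  names(mirna_seqs) <- mirna_ids

  edge_map <- split(edges$mirna_id, edges$target_id)
  site_dict <- Biostrings::PDict(Biostrings::DNAStringSet(sites))

  target_seqs <- vapply(target_ids, function(tid) {
    plant_target_sequence(
      length = spec$target_length,
      required = unname(sites[edge_map[[tid]]]),
      mirna_of_site = mirna_ids,
      allowed = edge_map[[tid]] %||% character(0),
      site_dict = site_dict,
      all_mirnas = mirna_ids
    )
  }, character(1))
  names(target_seqs) <- target_ids

  list(mirna = mirna_seqs, targets = target_seqs)
}

# build one target sequence: plant `required` sites (>= 7 bp apart), then
# iteratively redraw any position window matching a site whose miRNA is not
# in `allowed`, keeping planted positions fixed
plant_target_sequence <- function(length, required, mirna_of_site, allowed,
                                  site_dict, all_mirnas) {
  n_req <- length(required)
  if ((n_req * 14) > length) {
    abort("target_length too short for the required seed sites.")
  }
  chars <- sample(DNA_BASES, length, replace = TRUE)
  protected <- logical(length)
  if (n_req > 0) {
    # non-overlapping slots with >= 7 bp separation
    slot_starts <- sort(sample.int(length - 6L, n_req * 4))
    chosen <- integer(0)
    for (s in slot_starts) {
      if (all(abs(s - chosen) >= 14)) chosen <- c(chosen, s)
      if (length(chosen) == n_req) break
    }
    if (length(chosen) < n_req) {
      chosen <- seq(1L, by = 14L, length.out = n_req)
    }
    for (i in seq_len(n_req)) {
      idx <- chosen[i]:(chosen[i] + 6L)
      chars[idx] <- strsplit(required[i], "")[[1]]
      protected[idx] <- TRUE
    }
  }
  for (iter in 1:200) {
    seq_str <- paste(chars, collapse = "")
    hits <- Biostrings::matchPDict(site_dict, Biostrings::DNAString(seq_str))
    offending <- integer(0)
    for (j in seq_along(hits)) {
      if (all_mirnas[j] %in% allowed) next
      st <- BiocGenerics::start(hits[[j]])
      offending <- c(offending, st)
    }
    if (length(offending) == 0) return(seq_str)
    for (st in offending) {
      idx <- st:(st + 6L)
      free <- idx[!protected[idx]]
      chars[free] <- sample(DNA_BASES, length(free), replace = TRUE)
    }
  }
  abort("failed to scrub forbidden seed sites; increase target_length.")
}
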