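#' Four-step lncRNA candidate filter
#'
#' Applies, in order, the four selection steps used to nominate lncRNA
#' candidates from assembled transcripts:
#' 1. mature transcript length >= `lnc_min_len` and exon count >=
#'    `lnc_min_exons` (both inclusive);
#' 2. read coverage >= `lnc_min_cov` in at least one sample (the `coverage`
#'    column holds the per-transcript maximum over samples);
#' 3. removal of known non-lncRNA annotations (any biotype other than
#'    `lncRNA_candidate`);
#' 4. the coding-potential consensus over four classifiers (CNCI, CPC,
#'    Pfam, PhyloCSF): with `coding_filter = "all"` (default) a transcript
#'    is removed only when all four call it coding; `"any"` removes
#'    transcripts any classifier calls coding.
#'
#' Each step is a pure predicate, so the surviving set does not depend on
#' step order; the rejection log, however, reports survivors after each
#' step in the order 1 to 4. Records reaching step 4 without the four
#' classifier columns are a configuration error.
#'
#' @param records Tibble of transcript records with columns `transcript_id`,
#'   `length`, `exon_count`, `coverage`, `biotype` and the classifier
#'   columns `cnci`, `cpc`, `pfam`, `phylocsf` (logical; `TRUE` = called
#'   coding).
#' @param config A [cerna_config()]; `coding_filter` in the config is the
#'   default mode.
#' @return A list of class `lncrna_filter` with elements `kept` (tibble of
#'   surviving records), `rejected` (tibble with a `rejected_at_step`
#'   column) and `log` (per-step counts).
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   transcript_id = c("t1", "t2"), length = c(199, 500),
#'   exon_count = c(2, 3), coverage = c(5, 10),
#'   biotype = "lncRNA_candidate",
#'   cnci = FALSE, cpc = FALSE, pfam = FALSE, phylocsf = FALSE
#' )
#' filter_lncrna_candidates(recs)$log
filter_lncrna_candidates <- function(records, config = cerna_config()) {
  need <- c("transcript_id", "length", "exon_count", "coverage", "biotype")
  stopifnot(all(need %in% names(records)))
  mode <- config$coding_filter

  steps <- list(
    list(step = 1L,
         desc = sprintf("length >= %d and exons >= %d",
                        config$lnc_min_len, config$lnc_min_exons),
         pred = function(r) r$length >= config$lnc_min_len &
           r$exon_count >= config$lnc_min_exons),
    list(step = 2L,
         desc = sprintf("coverage >= %g in at least one sample",
                        config$lnc_min_cov),
         pred = function(r) r$coverage >= config$lnc_min_cov),
    list(step = 3L,
         desc = "known non-lncRNA annotations removed",
         pred = function(r) r$biotype == "lncRNA_candidate"),
    list(step = 4L,
         desc = sprintf("coding-potential consensus (mode '%s')", mode),
         pred = function(r) {
           calls <- c("cnci", "cpc", "pfam", "phylocsf")
           if (!all(calls %in% names(r)) ||
               anyNA(unlist(r[calls]))) {
             abort(paste("records reached the coding-potential step without",
                         "the four classifier calls."))
           }
           m <- as.matrix(r[calls])
           if (mode == "all") !apply(m, 1, all) else !apply(m, 1, any)
         })
  )

  current <- records
  rejected <- records[0, ]
  rejected$rejected_at_step <- integer(0)
  log <- tibble(step = integer(0), description = character(0),
                n_in = integer(0), n_rejected = integer(0),
                n_out = integer(0))
  for (s in steps) {
    if (nrow(current) == 0) {
      keep <- logical(0)
    } else {
      keep <- s$pred(current)
    }
    rej <- current[!keep, , drop = FALSE]
    if (nrow(rej) > 0) rej$rejected_at_step <- s$step
    rejected <- bind_rows(rejected, rej)
    log <- bind_rows(log, tibble(
      step = s$step, description = s$desc,
      n_in = nrow(current), n_rejected = sum(!keep), n_out = sum(keep)
    ))
    current <- current[keep, , drop = FALSE]
  }
  inform(sprintf(
    "lncRNA filter (coding-potential mode '%s'): %d of %d records kept.",
    mode, nrow(current), nrow(records)
  ))
  structure(list(kept = current, rejected = rejected, log = log),
            class = "lncrna_filter")
}

#' @export
print.lncrna_filter <- function(x, ...) {
  cat("<lncrna_filter>\n")
  print(x$log)
  cat(sprintf("kept: %d record(s)\n", nrow(x$kept)))
  invisible(x)
}
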