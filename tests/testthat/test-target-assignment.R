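iv <- function(id, chrom, start, end) {
  tibble::tibble(transcript_id = id, chromosome = chrom,
                 start = start, end = end)
}

test_that("cis window boundary is inclusive at exactly 100 kb", {
  lnc <- iv("lnc1", "chr1", 500000, 501000)
  genes <- dplyr::bind_rows(
    iv("g_at_window", "chr1", 300000, 400000),   # gap exactly 100,000
    iv("g_past_window", "chr1", 299999, 399999), # gap 100,001
    iv("g_overlap", "chr1", 500500, 502000),     # overlapping
    iv("g_downstream", "chr1", 550000, 551000),  # inside window, after
    iv("g_other_chrom", "chr2", 500000, 501000)
  )
  hits <- cis_targets(lnc, genes, window_bp = 100000)
  expect_setequal(hits$gene_id,
                  c("g_at_window", "g_overlap", "g_downstream"))
  expect_equal(hits$distance[hits$gene_id == "g_at_window"], -100000)
  expect_equal(hits$distance[hits$gene_id == "g_overlap"], 0)
  expect_equal(hits$distance[hits$gene_id == "g_downstream"], 49000)
})

test_that("cis gap is symmetric in which interval is the query", {
  set.seed(21)
  a <- iv(sprintf("a%d", 1:20), "chr1",
          s <- sample.int(1e6, 20), s + sample.int(5000, 20))
  b <- iv(sprintf("b%d", 1:20), "chr1",
          s2 <- sample.int(1e6, 20), s2 + sample.int(5000, 20))
  ab <- cis_targets(a, b, 50000)
  ba <- cis_targets(b, a, 50000)
  expect_setequal(paste(ab$lncrna_id, ab$gene_id),
                  paste(ba$gene_id, ba$lncrna_id))
  # distances mirror
  m <- match(paste(ab$lncrna_id, ab$gene_id),
             paste(ba$gene_id, ba$lncrna_id))
  expect_equal(ab$distance, -ba$distance[m])
})

trans_fix <- function(lnc_vals, gene_vals) {
  mk <- function(vals, id, class) {
    mat <- matrix(vals, nrow = 1, dimnames = list(id, NULL))
    colnames(mat) <- paste0(rep(c("dry", "early", "peak"), each = 3),
                            "_", 1:3)
    design <- tibble::tibble(
      sample = colnames(mat),
      condition = rep(c("dry", "early", "peak"), each = 3),
      replicate = rep(1:3, 3)
    )
    expression_matrix(mat, design, class,
                      conditions = c("dry", "early", "peak"))
  }
  list(lnc = mk(lnc_vals, "lnc1", "lncRNA"),
       gene = mk(gene_vals, "g1", "mRNA"))
}

test_that("trans correlation is strict at the threshold and scale-robust", {
  v <- c(1, 2, 4, 8, 16, 32, 64, 128, 256)
  # gene = 2 x lncRNA on the linear scale: r = 1 on the log scale
  fx <- trans_fix(v, 2 * v)
  hits <- trans_targets(fx$lnc, fx$gene, min_abs_r = 0.95,
                        pseudocount = 1e-9)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$r, 1)

  # multiplying a profile by a positive constant leaves r unchanged
  fx2 <- trans_fix(v, 17 * v)
  expect_equal(trans_targets(fx2$lnc, fx2$gene, 0.95,
                             pseudocount = 1e-9)$r, 1)

  # the gate is strict: |r| equal to the threshold is excluded. Tested at
  # an exactly representable correlation: cor((1,2,3), (1,3,2)) = 1/2.
  mk3 <- function(vals, id, class) {
    mat <- matrix(vals, nrow = 1, dimnames = list(id, NULL))
    colnames(mat) <- paste0("dry_", 1:3)
    design <- tibble::tibble(sample = colnames(mat), condition = "dry",
                             replicate = 1:3)
    expression_matrix(mat, design, class, conditions = "dry")
  }
  l3 <- mk3(c(1, 2, 3), "lnc1", "lncRNA")
  g3 <- mk3(c(1, 3, 2), "g1", "mRNA")
  at_thr <- trans_targets(l3, g3, min_abs_r = 0.5, log_scale = FALSE)
  expect_equal(nrow(at_thr), 0)
  below_thr <- trans_targets(l3, g3, min_abs_r = 0.49, log_scale = FALSE)
  expect_equal(below_thr$r, 0.5)

  # and around the default 0.95 threshold
  set.seed(1)
  x <- rnorm(9)
  resid <- residuals(lm(rnorm(9) ~ x))
  mkr <- function(r) {
    g <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(resid)[, 1]
    trans_fix(2^x, 2^g)
  }
  fx_lo <- mkr(0.93)
  expect_equal(nrow(trans_targets(fx_lo$lnc, fx_lo$gene, 0.95,
                                  pseudocount = 1e-9)), 0)
  fx_hi <- mkr(0.99)
  expect_equal(nrow(trans_targets(fx_hi$lnc, fx_hi$gene, 0.95,
                                  pseudocount = 1e-9)), 1)
})

test_that("constant profiles and mismatched designs yield no/illegal edges", {
  v <- c(1, 2, 4, 8, 16, 32, 64, 128, 256)
  fx <- trans_fix(v, rep(5, 9))
  expect_equal(nrow(trans_targets(fx$lnc, fx$gene, 0.95)), 0)

  fx2 <- trans_fix(v, v)
  bad_gene <- fx2$gene |> dplyr::filter(replicate != "3")
  expect_error(trans_targets(fx2$lnc, bad_gene, 0.95), "designs")
})

test_that("seed scanning matches a hand reverse-complement and rejects short miRNAs", {
  # miRNA 5'-UAGCAGCAC...: seed AGCAGCA, site revcomp TGCTGCT
  mirna <- c(m1 = "UAGCAGCACGUAAAUAUUGGCG")
  target <- c(t1 = "AAAATGCTGCTAAAA", t2 = "AAAACCCCCCCAAAA")
  res <- scan_mre(mirna, target)
  expect_equal(res$hits$target_id, "t1")
  expect_equal(res$hits$site_start, 5L)
  expect_equal(res$hits$site_type, "7mer-seed")
  expect_equal(brute_seed_scan(mirna, target["t1"]), 5L)
  expect_length(brute_seed_scan(mirna, target["t2"]), 0)

  expect_error(scan_mre(c(m = "UAGCAGC"), target), "shorter than 8")
  expect_error(scan_mre(c(m = "UAGCAGCAX"), target), "non-ACGU")
})

test_that("DNA and RNA alphabets are equivalent to the scanner", {
  rna <- c(m1 = "UAGCAGCACGUAAAUAUUGGCG")
  dna <- c(m1 = "TAGCAGCACGTAAATATTGGCG")
  target <- c(t1 = "GGGTGCTGCTGGGTGCTGCTGG")
  expect_equal(scan_mre(rna, target)$hits, scan_mre(dna, target)$hits)
  # overlapping sites are all reported
  expect_equal(scan_mre(rna, target)$hits$site_start, c(4L, 14L))
})

test_that("scan_mre agrees with the brute-force oracle on random fixtures", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  for (i in 1:25) {
    mir <- setNames(
      vapply(1:3, function(j) paste(sample(bases, 22, TRUE), collapse = ""),
             character(1)),
      paste0("m", 1:3)
    )
    tgt <- setNames(
      vapply(1:4, function(j) paste(sample(bases, 60, TRUE), collapse = ""),
             character(1)),
      paste0("t", 1:4)
    )
    got <- scan_mre(mir, tgt)$hits
    want <- dplyr::bind_rows(lapply(names(mir), function(mm) {
      dplyr::bind_rows(lapply(names(tgt), function(tt) {
        pos <- brute_seed_scan(mir[[mm]], tgt[[tt]])
        if (length(pos) == 0) return(NULL)
        tibble::tibble(mirna_id = mm, target_id = tt, site_start = pos,
                       site_type = "7mer-seed")
      }))
    }))
    if (nrow(want) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want |> dplyr::arrange(target_id, site_start, mirna_id)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  }
})
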