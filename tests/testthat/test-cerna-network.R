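test_that("hypergeometric p-value reproduces hand-enumerated cases", {
  # all 3 of the mRNA's miRNAs are the lncRNA's 3: 1/C(10,3) draws share all
  expect_equal(hypergeom_pvalue(10, 3, 3, 3), 1 / choose(10, 3),
               tolerance = 1e-12)
  # brute-force: (C(2,1)C(3,1) + C(2,2)C(3,0)) / C(5,2) = 7/10
  expect_equal(hypergeom_pvalue(5, 2, 2, 1), 0.7, tolerance = 1e-12)
  # c = 0 sums the whole support
  expect_identical(hypergeom_pvalue(100, 10, 20, 0), 1)
  # K = n = c = 1 reduces to n/N
  expect_equal(hypergeom_pvalue(100, 1, 1, 1), 0.01, tolerance = 1e-14)
  expect_equal(hypergeom_pvalue(1046, 1, 1, 1), 1 / 1046,
               tolerance = 1e-14)
})

test_that("hypergeometric domain errors are raised", {
  expect_error(hypergeom_pvalue(10, 3, 3, 4), "min\\(K, n\\)")
  expect_error(hypergeom_pvalue(10, 11, 3, 1), "universe")
  expect_error(hypergeom_pvalue(10, 3, 11, 1), "universe")
  expect_error(hypergeom_pvalue(10, -1, 3, 0), "non-negative")
})

test_that("p is non-increasing in the shared count and matches phyper", {
  set.seed(13)
  for (i in 1:50) {
    N <- sample(5:300, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    cs <- 0:min(K, n)
    ps <- hypergeom_pvalue(N, K, n, cs)
    expect_true(all(diff(ps) <= 1e-12))
    # independent distribution-function cross-check
    expect_equal(ps, stats::phyper(cs - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

de_stub <- function(...) {
  # minimal DE table marking every listed feature DE in one comparison
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(feature_id = r$ids, feature_class = r$class,
                   comparison = "early_vs_dry", is_de = TRUE)
  }))
}

test_that("a single fully shared miRNA gives p = n/N and is retained", {
  edges <- tibble::tibble(
    mirna_id = c("miR1", "miR1"),
    target_id = c("lncA", "geneB"),
    target_class = c("lncRNA", "mRNA"),
    score = NA_real_
  )
  de <- de_stub(list(ids = "miR1", class = "miRNA"),
                list(ids = "lncA", class = "lncRNA"),
                list(ids = "geneB", class = "mRNA"))
  cfg <- cerna_config(n_total_mirnas = 100)
  pairs <- build_candidate_pairs(edges, de, cfg)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$c, 1L)
  expect_equal(pairs$K, 1L)
  expect_equal(pairs$n, 1L)
  expect_equal(pairs$p, 0.01)
  expect_true(pairs$significant)
})

test_that("disjoint target sets yield no candidate pair", {
  edges <- tibble::tibble(
    mirna_id = c("miR1", "miR2"),
    target_id = c("lncA", "geneB"),
    target_class = c("lncRNA", "mRNA"),
    score = NA_real_
  )
  de <- de_stub(list(ids = c("miR1", "miR2"), class = "miRNA"),
                list(ids = "lncA", class = "lncRNA"),
                list(ids = "geneB", class = "mRNA"))
  pairs <- build_candidate_pairs(edges, de, cerna_config())
  expect_equal(nrow(pairs), 0)
})

test_that("the miRNA universe defaults to the supplied table and is checkable", {
  edges <- tibble::tibble(
    mirna_id = c("miR1", "miR1", "miR2", "miR3"),
    target_id = c("lncA", "geneB", "geneC", "geneC"),
    target_class = c("lncRNA", "mRNA", "mRNA", "mRNA"),
    score = NA_real_
  )
  de <- de_stub(list(ids = c("miR1", "miR2", "miR3"), class = "miRNA"),
                list(ids = "lncA", class = "lncRNA"),
                list(ids = c("geneB", "geneC"), class = "mRNA"))
  pairs <- build_candidate_pairs(edges, de, cerna_config())
  expect_equal(unique(pairs$N), 3L) # distinct miRNAs in the table
  expect_error(
    build_candidate_pairs(edges, de, cerna_config(n_total_mirnas = 1)),
    "smaller than a node degree"
  )
})

trend_stub <- function(...) {
  rows <- list(...)
  tibble::tibble(
    feature_id = names(rows),
    feature_class = NA_character_,
    directions = unname(rows),
    pattern = vapply(rows, paste, character(1), collapse = "/")
  )
}

mk_pair <- function(shared, c = length(shared), K = c, n = c, N = 200L,
                    p = NULL) {
  p <- p %||% hypergeom_pvalue(N, K, n, c)
  tibble::tibble(
    lncrna_id = "lncA", mrna_id = "geneB", comparison = "early_vs_dry",
    shared_mirnas = list(shared), c = as.integer(c), K = as.integer(K),
    n = as.integer(n), N = as.integer(N), p = p, q = p, significant = TRUE
  )
}

test_that("the canonical sponge pattern survives trend pruning", {
  trends <- trend_stub(
    lncA = c("up", "up"), geneB = c("up", "up"), miR1 = c("down", "down")
  )
  out <- trend_prune(mk_pair("miR1"), trends, cerna_config())
  expect_true(out$trend_consistent)
  expect_true(out$kept)
  expect_equal(out$c, 1L)
})

test_that("a same-trend miRNA is dropped, its pair re-scored and pruned", {
  trends <- trend_stub(
    lncA = c("up", "up"), geneB = c("up", "up"), miR1 = c("up", "up")
  )
  out <- trend_prune(mk_pair("miR1"), trends, cerna_config())
  expect_equal(out$c, 0L)
  expect_equal(out$n_dropped_mirnas, 1L)
  expect_false(out$kept)
})

test_that("a flat or non-mirrored miRNA leaves the pair inconsistent", {
  trends <- trend_stub(
    lncA = c("up", "up"), geneB = c("up", "up"), miR1 = c("flat", "flat")
  )
  out <- trend_prune(mk_pair("miR1"), trends, cerna_config())
  expect_equal(out$c, 1L) # not dropped: its trend differs from the targets'
  expect_false(out$trend_consistent)
  expect_false(out$kept)

  # lncRNA and mRNA disagreeing in trend also fails
  trends2 <- trend_stub(
    lncA = c("up", "up"), geneB = c("up", "down"), miR1 = c("down", "down")
  )
  expect_false(trend_prune(mk_pair("miR1"), trends2, cerna_config())$kept)
})

test_that("re-scoring after a miRNA drop never decreases p; degrees follow policy", {
  trends <- trend_stub(
    lncA = c("up", "up"), geneB = c("up", "up"),
    miR1 = c("down", "down"), miR2 = c("up", "up")
  )
  pair <- mk_pair(c("miR1", "miR2"), c = 2, K = 3, n = 4, N = 50)
  p0 <- pair$p
  out <- trend_prune(pair, trends, cerna_config())
  expect_equal(out$c, 1L)
  expect_equal(out$shared_mirnas[[1]], "miR1")
  # default policy: degrees are retained, only c shrinks
  expect_equal(out$K, 3L)
  expect_equal(out$n, 4L)
  expect_gte(out$p, p0)
  expect_equal(out$p, hypergeom_pvalue(50, 3, 4, 1))
  expect_true(out$kept)

  full <- trend_prune(pair, trends, cerna_config(rescore = "full"))
  expect_equal(full$K, 2L)
  expect_equal(full$n, 3L)
  expect_equal(full$p, hypergeom_pvalue(50, 2, 3, 1))
})

test_that("network summaries count distinct entities deterministically", {
  empty <- summarize_network(mk_pair("miR1")[0, ])
  expect_equal(empty$n_pairs, 0)
  expect_equal(empty$n_mirnas, 0)

  one <- summarize_network(mk_pair(c("miR1", "miR2"), c = 2, K = 2, n = 2))
  expect_equal(one$n_pairs[one$comparison == "overall"], 1)
  expect_equal(one$n_mrnas[one$comparison == "overall"], 1)
  expect_equal(one$n_mirnas[one$comparison == "overall"], 2)
  expect_equal(one$n_lncrnas[one$comparison == "overall"], 1)
})

test_that("end-to-end network construction recovers generator bookkeeping", {
  sim <- simulate_cerna_dataset(small_spec(seed = 15L))
  run <- suppressMessages(run_cerna_pipeline(sim = sim))
  net <- run$network
  # every surviving pair member was called DE in its comparison
  de_key <- run$de |> dplyr::filter(is_de)
  for (i in seq_len(nrow(net$network))) {
    row <- net$network[i, ]
    cmp_de <- de_key$feature_id[de_key$comparison == row$comparison]
    expect_true(row$lncrna_id %in% cmp_de)
    expect_true(row$mrna_id %in% cmp_de)
    expect_true(all(row$shared_mirnas[[1]] %in% cmp_de))
  }
  # glance/tidy are consistent with the summary table
  gl <- glance(net)
  ov <- net$summary[net$summary$comparison == "overall", ]
  expect_equal(gl$n_pairs, ov$n_pairs)
  expect_equal(nrow(tidy(net)), nrow(net$network))
})
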