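#' Hypergeometric shared-miRNA p-value
#'
#' Probability of observing at least `c` shared miRNAs between the target
#' sets of a lncRNA and an mRNA, when the mRNA's `n` targeting miRNAs are a
#' uniform draw from a universe of `N` miRNAs of which `K` target the
#' lncRNA:
#' \deqn{P = \sum_{i=c}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}
#'       {\binom{N}{n}}}
#' Computed in log space (`lchoose` plus a log-sum-exp reduction) for
#' numerical stability; exact for the integer inputs arising here.
#' Vectorised over its arguments.
#'
#' @param N miRNA universe size.
#' @param K Number of miRNAs targeting the lncRNA.
#' @param n Number of miRNAs targeting the mRNA.
#' @param c Number of shared miRNAs.
#' @return P-value(s) in \[0, 1\]; `c = 0` gives exactly 1.
#' @export
#' @examples
#' hypergeom_pvalue(10, 3, 3, 3) # 1 / choose(10, 3)
#' hypergeom_pvalue(5, 2, 2, 1)  # 7/10
hypergeom_pvalue <- function(N, K, n, c) {
  args <- vctrs_recycle(N = N, K = K, n = n, c = c)
  with(args, {
    if (any(c < 0) || any(K < 0) || any(n < 0) || any(N < 1)) {
      abort("hypergeometric parameters must be non-negative with N >= 1.")
    }
    if (any(K > N) || any(n > N)) {
      abort("degrees K and n cannot exceed the universe size N.")
    }
    if (any(c > pmin(K, n))) {
      abort("shared count c cannot exceed min(K, n).")
    }
    vapply(seq_along(N), function(j) {
      if (c[j] == 0) return(1)
      i <- c[j]:min(K[j], n[j])
      lt <- lchoose(K[j], i) + lchoose(N[j] - K[j], n[j] - i) -
        lchoose(N[j], n[j])
      lt <- lt[is.finite(lt)]
      if (length(lt) == 0) return(0)
      m <- max(lt)
      min(1, exp(m + log(sum(exp(lt - m)))))
    }, numeric(1))
  })
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, rep_len, length.out = len)
}

#' Candidate ceRNA pairs from a DE-restricted target table
#'
#' Forms every (lncRNA, mRNA) pair sharing at least one differentially
#' expressed miRNA, separately for each pairwise period comparison (a pair
#' enters a comparison when the lncRNA, the mRNA and the shared miRNA are
#' all differentially expressed in it). Each pair is scored with
#' [hypergeom_pvalue()] using the degrees over DE miRNAs (`K` for the
#' lncRNA, `n` for the mRNA, `c` shared) and the miRNA universe `N`, which
#' defaults to the number of distinct miRNAs in the full supplied target
#' table and can be fixed via `config$n_total_mirnas`. BH q-values are
#' computed over the candidate pairs of each comparison; the retention gate
#' is raw `p < cerna_alpha` by default (`config$cerna_gate = "q"` switches
#' to the adjusted value).
#'
#' @param edges Full target table tibble (`mirna_id`, `target_id`,
#'   `target_class`).
#' @param de Combined differential-expression results for all three classes
#'   (rows from [run_de_analysis()]).
#' @param config A [cerna_config()].
#' @return A tibble of candidate pairs (class `cerna_pairs`): `lncrna_id`,
#'   `mrna_id`, `comparison`, `shared_mirnas` (list-column), `c`, `K`, `n`,
#'   `N`, `p`, `q`, `significant`.
#' @export
build_candidate_pairs <- function(edges, de, config = cerna_config()) {
  N <- config$n_total_mirnas %||% n_distinct(edges$mirna_id)
  empty <- tibble(
    lncrna_id = character(0), mrna_id = character(0),
    comparison = character(0), shared_mirnas = list(),
    c = integer(0), K = integer(0), n = integer(0), N = integer(0),
    p = double(0), q = double(0), significant = logical(0)
  )
  if (nrow(edges) == 0 || nrow(de) == 0) {
    return(structure(empty, class = c("cerna_pairs", class(empty))))
  }
  comparisons <- unique(de$comparison)
  out <- map(comparisons, function(cmp) {
    de_cmp <- de |> filter(.data$comparison == cmp, .data$is_de)
    de_ids <- split(de_cmp$feature_id, de_cmp$feature_class)
    e <- edges |>
      filter(.data$mirna_id %in% (de_ids$miRNA %||% character(0)))
    e_lnc <- e |>
      filter(.data$target_class == "lncRNA",
             .data$target_id %in% (de_ids$lncRNA %||% character(0)))
    e_mrna <- e |>
      filter(.data$target_class == "mRNA",
             .data$target_id %in% (de_ids$mRNA %||% character(0)))
    if (nrow(e_lnc) == 0 || nrow(e_mrna) == 0) return(NULL)
    deg_lnc <- e_lnc |> count(.data$target_id, name = "K")
    deg_mrna <- e_mrna |> count(.data$target_id, name = "n")
    if (max(deg_lnc$K, deg_mrna$n) > N) {
      abort("miRNA universe N is smaller than a node degree.")
    }
    inner_join(
      e_lnc |> select(lncrna_id = "target_id", "mirna_id"),
      e_mrna |> select(mrna_id = "target_id", "mirna_id"),
      by = "mirna_id", relationship = "many-to-many"
    ) |>
      group_by(.data$lncrna_id, .data$mrna_id) |>
      summarise(shared_mirnas = list(sort(.data$mirna_id)),
                c = dplyr::n(), .groups = "drop") |>
      left_join(deg_lnc, by = c(lncrna_id = "target_id")) |>
      left_join(deg_mrna, by = c(mrna_id = "target_id")) |>
      mutate(comparison = cmp, N = N, .after = "mrna_id")
  }) |> bind_rows()
  if (nrow(out) == 0) {
    return(structure(empty, class = c("cerna_pairs", class(empty))))
  }
  out <- out |>
    arrange(.data$comparison, .data$lncrna_id, .data$mrna_id) |>
    mutate(p = hypergeom_pvalue(.data$N, .data$K, .data$n, .data$c)) |>
    group_by(.data$comparison) |>
    mutate(q = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    mutate(significant = if (config$cerna_gate == "p") {
      .data$p < config$cerna_alpha
    } else {
      .data$q < config$cerna_alpha
    }) |>
    select("lncrna_id", "mrna_id", "comparison", "shared_mirnas",
           "c", "K", "n", "N", "p", "q", "significant")
  structure(out, class = c("cerna_pairs", class(out)))
}

#' Trend-consistency pruning of ceRNA pairs
#'
#' Applies the sponge-signature consistency check on full expression-trend
#' profiles across the ordered periods. For each pair, any shared miRNA
#' whose direction vector equals that of both of its targets ("almost same
#' expression trends") is dropped from the shared set and the pair is
#' re-scored with the reduced shared count before the check (by default
#' only `c` shrinks; `config$rescore = "full"` also shrinks the degrees).
#' A pair is trend-consistent when the lncRNA and mRNA direction vectors
#' are identical and not all flat, and at least one remaining shared miRNA
#' shows the exactly sign-flipped profile. Pairs left with no shared miRNA
#' or failing the consistency check are pruned; the re-scored p and q are
#' reported but the significance gate is not re-applied.
#'
#' @param pairs A `cerna_pairs` tibble (typically the significant subset).
#' @param trends Trend profiles from [classify_trends()] covering every
#'   pair member; a missing feature is an error.
#' @param config A [cerna_config()].
#' @return The pairs tibble with updated `shared_mirnas`, `c`, `p`, `q` and
#'   new columns `n_dropped_mirnas`, `trend_consistent`, `kept`.
#' @export
trend_prune <- function(pairs, trends, config = cerna_config()) {
  if (nrow(pairs) == 0) {
    out <- pairs |>
      mutate(n_dropped_mirnas = integer(0), trend_consistent = logical(0),
             kept = logical(0))
    return(out)
  }
  dir_of <- setNames(trends$directions, trends$feature_id)
  lookup <- function(id) {
    d <- dir_of[[id]]
    if (is.null(d)) abort(sprintf("no trend profile for feature '%s'.", id))
    d
  }
  res <- pmap(
    list(pairs$lncrna_id, pairs$mrna_id, pairs$shared_mirnas,
         pairs$c, pairs$K, pairs$n, pairs$N),
    function(lnc, mrna, shared, c0, K0, n0, N0) {
      lnc_dir <- lookup(lnc)
      mrna_dir <- lookup(mrna)
      mir_dirs <- map(shared, lookup)
      same_trend <- map_lgl(mir_dirs, function(d) {
        identical(d, lnc_dir) && identical(d, mrna_dir)
      })
      remaining <- shared[!same_trend]
      n_drop <- sum(same_trend)
      c_new <- length(remaining)
      if (config$rescore == "full") {
        K_new <- K0 - n_drop
        n_new <- n0 - n_drop
      } else {
        K_new <- K0
        n_new <- n0
      }
      p_new <- if (c_new >= 1) {
        hypergeom_pvalue(N0, K_new, n_new, c_new)
      } else {
        1
      }
      anti <- map_lgl(mir_dirs[!same_trend], function(d) {
        identical(d, flip_direction(lnc_dir))
      })
      consistent <- identical(lnc_dir, mrna_dir) &&
        any(lnc_dir != "flat") && any(anti)
      list(shared_mirnas = remaining, c = c_new, K = K_new, n = n_new,
           p = p_new, n_dropped_mirnas = n_drop,
           trend_consistent = consistent)
    }
  )
  out <- pairs
  out$shared_mirnas <- map(res, "shared_mirnas")
  out$c <- map_int(res, ~ as.integer(.x$c))
  out$K <- map_int(res, ~ as.integer(.x$K))
  out$n <- map_int(res, ~ as.integer(.x$n))
  out$p <- map_dbl(res, "p")
  out$n_dropped_mirnas <- map_int(res, ~ as.integer(.x$n_dropped_mirnas))
  out$trend_consistent <- map_lgl(res, "trend_consistent")
  out <- out |>
    group_by(.data$comparison) |>
    mutate(q = p.adjust(.data$p, method = "BH")) |>
    ungroup()
  out$kept <- out$c >= 1 & out$trend_consistent
  out
}

#' Summarise a ceRNA network
#'
#' Distinct-entity counts (pairs, mRNAs, miRNAs in shared sets, lncRNAs)
#' per comparison and overall, in deterministic order.
#'
#' @param pairs A ceRNA pairs tibble (finalized network rows).
#' @return A tibble with one row per comparison plus an `overall` row.
#' @export
summarize_network <- function(pairs) {
  count_block <- function(df, label) {
    tibble(
      comparison = label,
      n_pairs = nrow(df),
      n_mrnas = n_distinct(df$mrna_id),
      n_mirnas = n_distinct(unlist(df$shared_mirnas)),
      n_lncrnas = n_distinct(df$lncrna_id)
    )
  }
  if (nrow(pairs) == 0) {
    return(count_block(pairs, "overall"))
  }
  per_cmp <- pairs |>
    group_by(.data$comparison) |>
    group_map(~ count_block(.x, .y$comparison)) |>
    bind_rows() |>
    arrange(.data$comparison)
  bind_rows(per_cmp, count_block(pairs, "overall"))
}

#' Build the full ceRNA network
#'
#' End-to-end network construction from a target table, combined
#' differential-expression results and trend profiles: candidate pairs are
#' formed and scored ([build_candidate_pairs()]), the significant ones are
#' pruned by trend consistency ([trend_prune()]), and the surviving pairs
#' form the network.
#'
#' @inheritParams build_candidate_pairs
#' @param trends Trend profiles from [classify_trends()] covering all
#'   classes.
#' @return An object of class `cerna_network` with elements `candidates`,
#'   `pairs` (significant candidates with pruning columns), `network`
#'   (final kept pairs), `summary`, `config`. Supports `tidy()`,
#'   `glance()`, `autoplot()` and `print()`.
#' @export
build_cerna_network <- function(edges, de, trends,
                                config = cerna_config()) {
  candidates <- build_candidate_pairs(edges, de, config)
  sig <- candidates |> filter(.data$significant)
  pruned <- trend_prune(sig, trends, config)
  network <- pruned |> filter(.data$kept)
  structure(
    list(
      candidates = candidates,
      pairs = pruned,
      network = network,
      summary = summarize_network(network),
      config = config
    ),
    class = "cerna_network"
  )
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("<cerna_network>\n")
  cat(sprintf("  candidate pairs:   %d\n", nrow(x$candidates)))
  cat(sprintf("  significant pairs: %d (gate %s < %g)\n",
              sum(x$candidates$significant), x$config$cerna_gate,
              x$config$cerna_alpha))
  cat(sprintf("  final network:     %d pair(s)\n", nrow(x$network)))
  print(x$summary)
  invisible(x)
}

#' Tidy a ceRNA network
#'
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return `tidy()` returns the final network as a flat tibble (shared
#'   miRNAs semicolon-joined); `glance()` returns a one-row summary.
#' @method tidy cerna_network
#' @export
tidy.cerna_network <- function(x, ...) {
  flatten_pairs(x$network)
}

#' @rdname tidy.cerna_network
#' @method glance cerna_network
#' @export
glance.cerna_network <- function(x, ...) {
  ov <- x$summary |> filter(.data$comparison == "overall")
  tibble(
    n_candidates = nrow(x$candidates),
    n_significant = sum(x$candidates$significant),
    n_pairs = ov$n_pairs,
    n_mrnas = ov$n_mrnas,
    n_mirnas = ov$n_mirnas,
    n_lncrnas = ov$n_lncrnas
  )
}
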