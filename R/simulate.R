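#' Simulation specification
#'
#' Describes a synthetic three-period, three-replicate transcriptome with
#' planted differential expression and planted ceRNA triplets. Defaults
#' emulate the bovine lactation study design the package implements at a
#' desk-friendly scale: 3 ordered periods (dry, early, peak) x 3 biological
#' replicates; log-normal FPKM/TPM-scale abundances with multiplicative
#' replicate noise; per-class planted differential-expression fractions set
#' to the study's observed DE rates (about 3% of mRNAs, 2% of lncRNAs, 5% of
#' miRNAs); and a mean miRNA out-degree of 6, about 1% of the simulated
#' target pool, matching the study's predicted-target density (roughly
#' 190 targets per miRNA out of ~21k genes).
#'
#' @param n_mrna,n_lncrna,n_mirna Feature counts per class.
#' @param n_conditions Number of ordered conditions (periods).
#' @param n_replicates Replicates per condition.
#' @param conditions Condition labels, in period order.
#' @param base_log2_mean,base_log2_sd Log2 parameters of the log-normal
#'   baseline abundance distribution.
#' @param noise_log2_sd Standard deviation (log2) of multiplicative
#'   replicate noise; must be positive.
#' @param planted_de_fraction Named vector (`mrna`, `lncrna`, `mirna`)
#'   giving the fraction of each class planted as differentially expressed
#'   beyond the ceRNA triplet members.
#' @param planted_log2_fc Planted log2 fold change per consecutive-period
#'   step for every planted feature.
#' @param n_planted_triplets Number of true ceRNA triplets
#'   (lncRNA, miRNA, mRNA): the miRNA condition means follow a random
#'   up/down pattern and both the lncRNA and the mRNA follow the sign-flipped
#'   pattern, the operational signature of miRNA sponging.
#' @param mirna_targets_per_mirna Mean number of additional random targets
#'   wired per miRNA (Poisson out-degree) beyond planted triplet edges.
#' @param target_length Length (nt) of simulated target sequences.
#' @param mirna_length Length (nt) of simulated mature miRNA sequences.
#' @param rng_seed Integer seed; a fixed seed makes every generated object
#'   bit-identical across runs (Mersenne-Twister).
#'
#' @return A list of class `sim_spec`.
#' @export
simulation_spec <- function(n_mrna = 500, n_lncrna = 100, n_mirna = 200,
                            n_conditions = 3, n_replicates = 3,
                            conditions = c("dry", "early", "peak"),
                            base_log2_mean = 5, base_log2_sd = 2,
                            noise_log2_sd = 0.25,
                            planted_de_fraction = c(mrna = 0.03,
                                                    lncrna = 0.02,
                                                    mirna = 0.05),
                            planted_log2_fc = 3,
                            n_planted_triplets = 20,
                            mirna_targets_per_mirna = 6,
                            target_length = 500,
                            mirna_length = 22,
                            rng_seed = 1L) {
  if (length(conditions) != n_conditions) {
    conditions <- paste0("cond", seq_len(n_conditions))
  }
  spec <- list(
    n_mrna = n_mrna, n_lncrna = n_lncrna, n_mirna = n_mirna,
    n_conditions = n_conditions, n_replicates = n_replicates,
    conditions = conditions,
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    noise_log2_sd = noise_log2_sd,
    planted_de_fraction = planted_de_fraction,
    planted_log2_fc = planted_log2_fc,
    n_planted_triplets = n_planted_triplets,
    mirna_targets_per_mirna = mirna_targets_per_mirna,
    target_length = target_length,
    mirna_length = mirna_length,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_spec(spec)
  structure(spec, class = "sim_spec")
}

validate_sim_spec <- function(spec) {
  stopifnot(
    spec$n_mrna > 0, spec$n_lncrna > 0, spec$n_mirna > 0,
    spec$n_conditions >= 2, spec$n_replicates >= 2,
    spec$noise_log2_sd > 0,
    spec$planted_log2_fc >= 0,
    all(spec$planted_de_fraction >= 0),
    all(spec$planted_de_fraction <= 1),
    spec$mirna_targets_per_mirna >= 0,
    spec$target_length >= 30, spec$mirna_length >= 8
  )
  if (spec$n_planted_triplets >
      min(spec$n_lncrna, spec$n_mrna, spec$n_mirna)) {
    abort("more planted triplets than available lncRNA/mRNA/miRNA ids.")
  }
  invisible(spec)
}

sim_ids <- function(spec) {
  list(
    mrna = sprintf("mRNA_%04d", seq_len(spec$n_mrna)),
    lncrna = sprintf("lnc_%04d", seq_len(spec$n_lncrna)),
    mirna = sprintf("miR_%04d", seq_len(spec$n_mirna))
  )
}

# random up/down step pattern as a +1/-1 vector of length n_conditions - 1
draw_pattern <- function(n_steps) sample(c(1L, -1L), n_steps, replace = TRUE)

pattern_string <- function(steps) {
  paste(ifelse(steps > 0, "up", "down"), collapse = "/")
}

#' Generate a synthetic ceRNA dataset
#'
#' Draws annotation, expression matrices for the three RNA classes, a miRNA
#' target table and the ground truth behind them. Planted ceRNA triplets
#' obey the sponge signature: across the ordered conditions, the miRNA
#' condition means follow a drawn up/down pattern with
#' `planted_log2_fc` log2 units per step, while both the lncRNA and mRNA
#' follow the sign-flipped pattern. Additional features are planted as
#' differentially expressed without triplet structure; all remaining
#' features have flat condition means. Replicate values are the condition
#' mean times log-normal noise. A fixed `rng_seed` reproduces the dataset
#' bit-identically.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `cerna_sim` with elements `spec`, `records`
#'   (transcript annotation tibble), `exons` (exon models for GTF export),
#'   `expr` (named list of `cerna_expr` tibbles: `mRNA`, `lncRNA`, `miRNA`),
#'   `edges` (target table) and `truth` (ground truth: `planted_triplets`,
#'   `planted_de`, `planted_edges`).
#' @export
#' @examples
#' sim <- simulate_cerna_dataset(simulation_spec(
#'   n_mrna = 40, n_lncrna = 10, n_mirna = 15, n_planted_triplets = 3
#' ))
#' sim$truth$planted_triplets
simulate_cerna_dataset <- function(spec) {
  simulate_dataset_impl(spec, planted = TRUE)
}

#' Generate a null dataset with no planted structure
#'
#' As [simulate_cerna_dataset()] but with every planting disabled: all
#' condition means are flat and target edges are wired uniformly at random.
#' The ground truth is empty. Used for false-positive-rate calibration.
#'
#' @param spec A [simulation_spec()].
#' @return A `cerna_sim` list with empty ground truth.
#' @export
simulate_null_dataset <- function(spec) {
  simulate_dataset_impl(spec, planted = FALSE)
}

simulate_dataset_impl <- function(spec, planted) {
  validate_sim_spec(spec)
  set.seed(spec$rng_seed, kind = "Mersenne-Twister")
  ids <- sim_ids(spec)
  k <- spec$n_conditions
  n_steps <- k - 1L
  fc <- spec$planted_log2_fc

  n_trip <- if (planted) spec$n_planted_triplets else 0L
  trip <- tibble(
    lncrna_id = character(0), mirna_id = character(0),
    mrna_id = character(0), mirna_pattern = character(0)
  )
  # per-feature condition-mean offsets (log2), flat by default
  offsets <- list(
    mrna = matrix(0, spec$n_mrna, k, dimnames = list(ids$mrna, NULL)),
    lncrna = matrix(0, spec$n_lncrna, k, dimnames = list(ids$lncrna, NULL)),
    mirna = matrix(0, spec$n_mirna, k, dimnames = list(ids$mirna, NULL))
  )
  planted_de <- tibble(feature_id = character(0), feature_class = character(0),
                       pattern = character(0))
  apply_pattern <- function(class, id, steps) {
    offsets[[class]][id, ] <<- c(0, cumsum(steps)) * fc
  }

  if (n_trip > 0) {
    trip_lnc <- sample(ids$lncrna, n_trip)
    trip_mrna <- sample(ids$mrna, n_trip)
    trip_mir <- sample(ids$mirna, n_trip)
    patterns <- map(seq_len(n_trip), ~ draw_pattern(n_steps))
    for (i in seq_len(n_trip)) {
      apply_pattern("mirna", trip_mir[i], patterns[[i]])
      apply_pattern("lncrna", trip_lnc[i], -patterns[[i]])
      apply_pattern("mrna", trip_mrna[i], -patterns[[i]])
    }
    trip <- tibble(
      lncrna_id = trip_lnc, mirna_id = trip_mir, mrna_id = trip_mrna,
      mirna_pattern = map_chr(patterns, pattern_string)
    )
    planted_de <- bind_rows(
      tibble(feature_id = trip_mir, feature_class = "miRNA",
             pattern = map_chr(patterns, pattern_string)),
      tibble(feature_id = trip_lnc, feature_class = "lncRNA",
             pattern = map_chr(patterns, ~ pattern_string(-.x))),
      tibble(feature_id = trip_mrna, feature_class = "mRNA",
             pattern = map_chr(patterns, ~ pattern_string(-.x)))
    )
  }

  if (planted) {
    frac <- spec$planted_de_fraction
    extra <- list(
      mrna = setdiff(ids$mrna, trip$mrna_id),
      lncrna = setdiff(ids$lncrna, trip$lncrna_id),
      mirna = setdiff(ids$mirna, trip$mirna_id)
    )
    class_label <- c(mrna = "mRNA", lncrna = "lncRNA", mirna = "miRNA")
    for (cl in c("mrna", "lncrna", "mirna")) {
      n_extra <- round(frac[[cl]] * length(ids[[cl]]))
      n_extra <- min(n_extra, length(extra[[cl]]))
      if (n_extra > 0) {
        chosen <- sample(extra[[cl]], n_extra)
        for (id in chosen) {
          steps <- draw_pattern(n_steps)
          apply_pattern(cl, id, steps)
          planted_de <- bind_rows(planted_de, tibble(
            feature_id = id, feature_class = class_label[[cl]],
            pattern = pattern_string(steps)
          ))
        }
      }
    }
  }

  # expression: baseline log2 mean per feature, offsets per condition,
  # multiplicative log-normal replicate noise
  make_expr <- function(class, feature_class) {
    fids <- ids[[class]]
    base <- rnorm(length(fids), spec$base_log2_mean, spec$base_log2_sd)
    log2_means <- offsets[[class]] + base
    grid <- crossing(
      feature_id = fids,
      condition = factor(spec$conditions, levels = spec$conditions),
      replicate = as.character(seq_len(spec$n_replicates))
    ) |> arrange(.data$feature_id, .data$condition, .data$replicate)
    mu <- log2_means[cbind(
      match(grid$feature_id, fids), as.integer(grid$condition)
    )]
    grid$abundance <- 2^(mu + rnorm(nrow(grid), 0, spec$noise_log2_sd))
    grid$feature_class <- feature_class
    validate_expression(grid)
  }
  expr <- list(
    mRNA = make_expr("mrna", "mRNA"),
    lncRNA = make_expr("lncrna", "lncRNA"),
    miRNA = make_expr("mirna", "miRNA")
  )

  # target edges: planted triplet edges plus Poisson background wiring
  planted_edges <- if (n_trip > 0) {
    bind_rows(
      tibble(mirna_id = trip$mirna_id, target_id = trip$lncrna_id,
             target_class = "lncRNA"),
      tibble(mirna_id = trip$mirna_id, target_id = trip$mrna_id,
             target_class = "mRNA")
    )
  } else {
    tibble(mirna_id = character(0), target_id = character(0),
           target_class = character(0))
  }
  all_targets <- c(ids$mrna, ids$lncrna)
  target_class_of <- setNames(
    c(rep("mRNA", spec$n_mrna), rep("lncRNA", spec$n_lncrna)), all_targets
  )
  bg <- map(seq_len(spec$n_mirna), function(i) {
    n_t <- min(rpois(1, spec$mirna_targets_per_mirna), length(all_targets))
    if (n_t == 0) return(NULL)
    tgts <- sample(all_targets, n_t)
    tibble(mirna_id = ids$mirna[i], target_id = tgts,
           target_class = unname(target_class_of[tgts]))
  })
  edges <- bind_rows(planted_edges, bind_rows(bg)) |>
    distinct(.data$mirna_id, .data$target_id, .keep_all = TRUE) |>
    mutate(score = NA_real_) |>
    arrange(.data$mirna_id, .data$target_id)

  ann <- simulate_annotation(spec, ids)

  truth <- list(
    planted_triplets = trip,
    planted_de = planted_de |> arrange(.data$feature_class, .data$feature_id),
    planted_edges = planted_edges |>
      arrange(.data$mirna_id, .data$target_id)
  )
  structure(
    list(spec = spec, records = ann$records, exons = ann$exons,
         expr = expr, edges = edges, truth = truth),
    class = "cerna_sim"
  )
}

# transcript models: mRNAs multi-exon coding, lncRNA candidates passing the
# 4-step filter, miRNA precursors single-exon with passing miRDeep2 scores
simulate_annotation <- function(spec, ids) {
  chroms <- paste0("chr", 1:5)
  one_class <- function(fids, feature_class) {
    n <- length(fids)
    exon_counts <- switch(feature_class,
      mRNA = sample(2:10, n, replace = TRUE),
      lncRNA = sample(2:4, n, replace = TRUE),
      miRNA = rep(1L, n)
    )
    chrom <- sample(chroms, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    start <- sample.int(5e7, n)
    exons <- map(seq_len(n), function(i) {
      kx <- exon_counts[i]
      widths <- switch(feature_class,
        mRNA = sample(100:300, kx, replace = TRUE),
        lncRNA = sample(150:400, kx, replace = TRUE),
        miRNA = sample(70:90, kx, replace = TRUE)
      )
      introns <- if (kx > 1) sample(200:2000, kx - 1, replace = TRUE) else integer(0)
      starts <- start[i] + cumsum(c(0L, head(widths, -1) + introns))
      tibble(
        transcript_id = fids[i], gene_id = paste0("g_", fids[i]),
        chromosome = chrom[i], strand = strand[i],
        start = starts, end = starts + widths - 1L
      )
    })
    exons <- bind_rows(exons)
    records <- exons |>
      group_by(.data$transcript_id) |>
      summarise(
        gene_id = dplyr::first(.data$gene_id),
        chromosome = dplyr::first(.data$chromosome),
        strand = dplyr::first(.data$strand),
        exon_count = dplyr::n(),
        length = sum(.data$end - .data$start + 1L),
        start = min(.data$start), end = max(.data$end),
        .groups = "drop"
      ) |>
      select("transcript_id", "gene_id", "chromosome", "strand",
             "start", "end", "exon_count", "length") |>
      mutate(
        feature_class = .env$feature_class,
        coverage = runif(dplyr::n(), 3, 50),
        biotype = switch(.env$feature_class, mRNA = "coding",
                         lncRNA = "lncRNA_candidate", miRNA = "known_ncRNA"),
        cnci = .env$feature_class == "mRNA",
        cpc = .env$feature_class == "mRNA",
        pfam = .env$feature_class == "mRNA",
        phylocsf = .env$feature_class == "mRNA",
        mirdeep2_score = if (.env$feature_class == "miRNA") 10 else NA_real_
      )
    list(records = records, exons = exons)
  }
  parts <- list(
    one_class(ids$mrna, "mRNA"),
    one_class(ids$lncrna, "lncRNA"),
    one_class(ids$mirna, "miRNA")
  )
  list(
    records = bind_rows(map(parts, "records")) |>
      arrange(.data$transcript_id),
    exons = bind_rows(map(parts, "exons")) |>
      arrange(.data$transcript_id, .data$start)
  )
}
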