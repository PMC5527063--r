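# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct enumeration, literal step-up formula,
# character-level substring search.

# Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j, clipped to 1
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exact hypergeometric tail by enumerating every n-subset of 1..N with the
# marked set 1..K
hyper_enum_oracle <- function(N, K, n, c) {
  if (n == 0 || K == 0) return(as.numeric(c == 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= c)
}

# literal urn: draw n balls from N (K marked) per replicate
urn_oracle <- function(N, K, n, c, reps) {
  mean(replicate(reps, sum(sample(N, n) <= K) >= c))
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# all-positions substring search for the seed site of one miRNA in one target
brute_seed_scan <- function(mirna, target) {
  mirna <- toupper(chartr("Uu", "Tt", mirna))
  target <- toupper(chartr("Uu", "Tt", target))
  site <- oracle_revcomp(substr(mirna, 2, 8))
  L <- nchar(target)
  if (L < 7) return(integer(0))
  pos <- seq_len(L - 6)
  pos[vapply(pos, function(i) substr(target, i, i + 6) == site, logical(1))]
}

flatten_pairs_for_test <- function(pairs) {
  pairs$shared_mirnas <- vapply(pairs$shared_mirnas, paste, character(1),
                                collapse = ";")
  as.data.frame(pairs)
}

# small deterministic fixture shared by several tests
small_spec <- function(seed = 1L, ...) {
  args <- list(n_mrna = 40, n_lncrna = 12, n_mirna = 15,
               n_planted_triplets = 4, target_length = 300,
               rng_seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(simulation_spec, args)
}
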