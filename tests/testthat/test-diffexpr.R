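make_expr <- function(mat, conditions, reps_per_cond, class = "mRNA") {
  design <- tibble::tibble(
    sample = colnames(mat),
    condition = rep(conditions, each = reps_per_cond),
    replicate = rep(seq_len(reps_per_cond), times = length(conditions))
  )
  expression_matrix(mat, design, class, conditions = conditions)
}

two_cond <- function(a, b, class = "mRNA") {
  mat <- rbind(f1 = c(a, b))
  colnames(mat) <- c(paste0("dry_", seq_along(a)),
                     paste0("early_", seq_along(b)))
  make_expr(mat, c("dry", "early"), length(a), class)
}

test_that("log2 fold change follows the pseudocount formula", {
  expect_equal(log2_fold_change(5, 10, 1), log2(11 / 6))
  expect_equal(log2_fold_change(7, 7, 0.5), 0)
  expect_equal(log2_fold_change(0, 0, 1), 0)
  # antisymmetry
  for (x in list(c(2, 9), c(0, 4), c(100, 3))) {
    expect_equal(log2_fold_change(x[1], x[2], 1),
                 -log2_fold_change(x[2], x[1], 1))
  }
  expect_error(log2_fold_change(-1, 2, 1), "non-negative")
  expect_error(log2_fold_change(1, 2, 0), "positive")
})

test_that("identical replicate vectors give p = 1 and no DE call", {
  expr <- two_cond(c(4, 4, 4), c(4, 4, 4))
  res <- de_test(expr, c("dry", "early"))
  expect_equal(res$p, 1)
  expect_false(res$is_de)
  expect_equal(res$log2_fc, 0)
})

test_that("a planted 8-fold change with low noise is called DE", {
  set.seed(42)
  hits <- vapply(1:30, function(i) {
    a <- 2^(3 + rnorm(3, 0, 0.1))
    b <- 2^(6 + rnorm(3, 0, 0.1)) # 8-fold up
    de_test(two_cond(a, b), c("dry", "early"))$is_de
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the miRNA gate needs p, fold change and miRDeep2 score together", {
  set.seed(7)
  a <- 2^(3 + rnorm(3, 0, 0.05))
  b <- 2^(6 + rnorm(3, 0, 0.05))
  expr <- two_cond(a, b, class = "miRNA")
  ok <- de_test(expr, c("dry", "early"), scores = c(f1 = 1.5))
  expect_true(ok$is_de)
  # low miRDeep2 score vetoes an otherwise significant call
  low <- de_test(expr, c("dry", "early"), scores = c(f1 = 0.5))
  expect_true(low$p < 0.05 && abs(low$log2_fc) > 1)
  expect_false(low$is_de)
  # unscored (known) miRNAs pass the score gate
  unscored <- de_test(expr, c("dry", "early"))
  expect_true(unscored$is_de)
  # fold change below 2x vetoes even with small p
  c_small <- 2^(3 + rnorm(3, 0, 0.01))
  d_small <- 2^(3.5 + rnorm(3, 0, 0.01)) # ~1.4-fold
  weak <- de_test(two_cond(c_small, d_small, "miRNA"), c("dry", "early"))
  expect_false(weak$is_de)
})

test_that("mRNA/lncRNA calls use the BH-adjusted q threshold", {
  set.seed(99)
  n <- 50
  mat <- 2^matrix(rnorm(n * 6, 5, 0.2), n)
  mat[1, 4:6] <- mat[1, 4:6] * 64
  rownames(mat) <- sprintf("f%02d", seq_len(n))
  colnames(mat) <- c(paste0("dry_", 1:3), paste0("early_", 1:3))
  expr <- make_expr(mat, c("dry", "early"), 3)
  res <- de_test(expr, c("dry", "early"))
  expect_true(res$is_de[res$feature_id == "f01"])
  expect_lt(sum(res$is_de), 5)
  expect_true(all(res$q >= res$p))
})

test_that("externally supplied p-values override the built-in test", {
  expr <- two_cond(c(4, 4, 4), c(4, 4, 4))
  res <- de_test(expr, c("dry", "early"),
                 pvalues = tibble::tibble(feature_id = "f1", p = 1e-6))
  expect_equal(res$p, 1e-6)
})

test_that("a condition with fewer than 2 replicates is an error", {
  mat <- rbind(f1 = c(1, 2, 3))
  colnames(mat) <- c("dry_1", "dry_2", "early_1")
  # build manually: dry has 2 reps, early has 1
  design <- tibble::tibble(sample = colnames(mat),
                           condition = c("dry", "dry", "early"),
                           replicate = c("1", "2", "1"))
  expr <- expression_matrix(mat, design, "mRNA",
                            conditions = c("dry", "early"))
  expect_error(de_test(expr, c("dry", "early")), "early.*2 replicates")
})

test_that("trend classification applies the epsilon band per step", {
  mk <- function(means) {
    mat <- rbind(f1 = rep(means, each = 2))
    colnames(mat) <- paste0(rep(c("dry", "early", "peak"), each = 2),
                            "_", 1:2)
    make_expr(mat, c("dry", "early", "peak"), 2)
  }
  cfg <- cerna_config(trend_epsilon = 0.1, pseudocount = 1e-9)
  t1 <- classify_trend(mk(c(1, 2, 4)), "f1", cfg)
  expect_equal(t1$directions[[1]], c("up", "up"))
  t2 <- classify_trend(mk(c(5, 5, 5)), "f1", cfg)
  expect_equal(t2$directions[[1]], c("flat", "flat"))
  # |log2(2.05/2)| ~= 0.036 <= 0.1 -> flat
  t3 <- classify_trend(mk(c(4, 2, 2.05)), "f1", cfg)
  expect_equal(t3$directions[[1]], c("down", "flat"))
  expect_equal(t3$pattern, "down/flat")
  expect_error(classify_trend(mk(c(1, 2, 4)), "nope", cfg), "unknown feature")
})

test_that("swapping conditions flips fold-change sign and trend direction", {
  set.seed(5)
  mat <- 2^matrix(rnorm(20 * 6, 5, 1), 20)
  rownames(mat) <- sprintf("f%02d", 1:20)
  colnames(mat) <- c(paste0("dry_", 1:3), paste0("early_", 1:3))
  expr <- make_expr(mat, c("dry", "early"), 3)
  fwd <- de_test(expr, c("dry", "early"))
  rev <- de_test(expr, c("early", "dry"))
  expect_equal(fwd$log2_fc, -rev$log2_fc)
  expect_equal(fwd$p, rev$p)

  expr_rev <- make_expr(mat[, c(4:6, 1:3)], c("early", "dry"), 3)
  tr_f <- classify_trends(expr, cerna_config(trend_epsilon = 0))
  tr_r <- classify_trends(expr_rev, cerna_config(trend_epsilon = 0))
  flip <- c(up = "down", down = "up", flat = "flat")
  expect_equal(unname(flip[tr_f$pattern]), tr_r$pattern)
})

test_that("BH adjustment matches the independent step-up oracle", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_stepup_oracle(p),
                 tolerance = 1e-12)
  }
})
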