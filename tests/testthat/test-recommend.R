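make_scores <- function(s, genes = paste0("g", seq_along(s)), label = "d1") {
  matrix(s, ncol = 1, dimnames = list(genes, label))
}

test_that("negative genes are ranked by score with id tie-breaks", {
  uni <- gene_universe(c("ga", "gb", "gc"))
  Y <- matrix(0, 3, 1, dimnames = list(uni$ids, "d1"))
  S <- matrix(c(0.9, 0.1, 0.5), 3, 1, dimnames = list(uni$ids, "d1"))
  rk <- rank_negative_genes(S, label_matrix(Y, uni, "d1"), "d1")
  expect_equal(rk$gene, c("ga", "gc", "gb"))

  # all positive: empty with warning
  Y1 <- matrix(1, 3, 1, dimnames = list(uni$ids, "d1"))
  expect_warning(rk0 <- rank_negative_genes(S, label_matrix(Y1, uni, "d1"), "d1"),
                 "no negative")
  expect_equal(nrow(rk0), 0)

  # tied scores fall back to lexicographic gene order
  S2 <- matrix(0.5, 3, 1, dimnames = list(uni$ids, "d1"))
  rk2 <- rank_negative_genes(S2, label_matrix(Y, uni, "d1"), "d1")
  expect_equal(rk2$gene, c("ga", "gb", "gc"))
  expect_error(rank_negative_genes(S, label_matrix(Y, uni, "d1"), "nope"),
               "unknown disease")
})

test_that("consensus requires the frequency threshold and is order-invariant", {
  uni <- gene_universe(sprintf("g%02d", 1:40))
  Y <- matrix(0, 40, 1, dimnames = list(uni$ids, "d1"))
  lab <- label_matrix(Y, uni, "d1")
  # 30 runs; gene g40 sneaks into the top 5 in exactly 19 runs
  runs <- lapply(1:30, function(r) {
    s <- seq(0.9, 0.1, length.out = 40)
    names(s) <- uni$ids
    if (r <= 19) s["g40"] <- 0.95
    recommendation_run(make_scores(s, uni$ids), lab, seed = r)
  })
  cons <- consensus_recommend(runs, top_k = 5, min_freq = 20)
  expect_false("g40" %in% cons$diseases$d1$gene)
  cons19 <- consensus_recommend(runs, top_k = 5, min_freq = 19)
  expect_true("g40" %in% cons19$diseases$d1$gene)
  expect_equal(cons19$diseases$d1$frequency[cons19$diseases$d1$gene == "g40"], 19L)

  # deterministic scorer: every recommended gene at full frequency,
  # and the result does not depend on run order
  det <- lapply(1:10, function(r) {
    recommendation_run(make_scores(seq(0.9, 0.1, length.out = 40), uni$ids), lab, r)
  })
  cd <- consensus_recommend(det, top_k = 5, min_freq = 10)
  expect_equal(nrow(cd$diseases$d1), 5)
  expect_true(all(cd$diseases$d1$frequency == 10))
  cd_rev <- consensus_recommend(rev(det), top_k = 5, min_freq = 10)
  expect_equal(cd$diseases$d1, cd_rev$diseases$d1)
  expect_equal(cd$rest_mean, cd_rev$rest_mean)

  # probability summaries are ordered Low <= Ave <= Hig
  tab <- cons19$diseases$d1
  expect_true(all(tab$low_p <= tab$ave_p + 1e-12))
  expect_true(all(tab$ave_p <= tab$hig_p + 1e-12))
})

test_that("recommendation confidence follows the pool-size formula", {
  expect_gt(recommendation_confidence(30, 19188), 99.8)
  expect_equal(recommendation_confidence(30, 19188), (1 - 30 / 19188) * 100)
  expect_equal(recommendation_confidence(0, 10), 100)
  expect_error(recommendation_confidence(11, 10))
})

test_that("the neighbour test separates blocks and calibrates under the null", {
  uni <- gene_universe(sprintf("g%02d", 1:80))
  Y <- matrix(0, 80, 1, dimnames = list(uni$ids, "d1"))
  lab <- label_matrix(Y, uni, "d1")
  # strong separation at reduced k: p equals the minimal exact tail
  set.seed(1)
  sep <- c(runif(5, 0.89, 0.91), runif(5, 0.09, 0.11), runif(70, 0, 0.05))
  runs <- list(recommendation_run(make_scores(sep, uni$ids), lab, 1))
  p <- neighbor_hypothesis_test(runs, "d1", top_k = 5)$p_value
  expect_equal(p, 1 / choose(10, 5)) # most extreme rank-sum arrangement

  # identical blocks: p near 1 under the greater alternative
  same <- rep(c(0.5, 0.4), each = 40)
  runs_same <- list(recommendation_run(make_scores(same, uni$ids), lab, 1))
  expect_gte(neighbor_hypothesis_test(runs_same, "d1", top_k = 5)$p_value, 0.95)

  # too few negatives: NA with warning
  Y2 <- matrix(1, 80, 1, dimnames = list(uni$ids, "d1"))
  Y2[1:8, 1] <- 0
  runs_small <- suppressWarnings(
    list(recommendation_run(make_scores(sep, uni$ids),
                            label_matrix(Y2, uni, "d1"), 1)))
  expect_warning(out <- neighbor_hypothesis_test(runs_small, "d1", top_k = 5),
                 "fewer than")
  expect_true(is.na(out$p_value))
})

test_that("neighbour-test p-values shrink as the planted separation grows", {
  uni <- gene_universe(sprintf("g%03d", 1:100))
  Y <- matrix(0, 100, 1, dimnames = list(uni$ids, "d1"))
  lab <- label_matrix(Y, uni, "d1")
  ps <- vapply(c(0.01, 0.05, 0.2), function(gap) {
    set.seed(42)
    base <- c(rep(0.5 + gap, 30), rep(0.5, 70)) # planted block separation
    runs <- lapply(1:5, function(r) {
      s <- pmin(pmax(base + rnorm(100, sd = 0.08), 0), 1) # per-run noise
      recommendation_run(make_scores(s, uni$ids), lab, r)
    })
    neighbor_hypothesis_test(runs, "d1", top_k = 30)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("the block test keeps its size under resampling from one distribution", {
  set.seed(7)
  rej <- mean(replicate(500, block_score_test(rnorm(30), rnorm(30)) < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})
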