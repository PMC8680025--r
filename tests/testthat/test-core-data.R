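test_that("gene universe enforces unique non-empty ids", {
  uni <- gene_universe(c("10", "20", "abc"))
  expect_length(uni, 3)
  expect_equal(gene_index(uni, c("abc", "10")), c(3L, 1L))
  expect_error(gene_universe(character()), "at least one")
  expect_error(gene_universe(c("a", "a")), "duplicate")
  expect_error(gene_index(uni, "missing"), "not in universe")
})

test_that("edge lists load symmetric adjacency with duplicate summation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "g1\tg2\t1"), f)
  net <- load_edge_list(f)
  expect_equal(net$A[1, 2], 1)
  expect_equal(net$A[2, 1], 1)
  expect_equal(diag(net$A), c(g1 = 0, g2 = 0))

  writeLines(c("g1\tg2\t1", "g2\tg1\t2"), f)
  net <- load_edge_list(f)
  expect_equal(net$A[1, 2], 3)
  expect_equal(net$A[2, 1], 3)

  writeLines(character(), f)
  net <- load_edge_list(f, universe = toy_universe(3))
  expect_equal(net$A, matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3))))

  writeLines("g1\tg2\t-1", f)
  expect_error(load_edge_list(f), "negative weight at row 1")
})

test_that("weight column defaults to one and self-loops are kept", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2", "g1\tg1"), f)
  net <- load_edge_list(f)
  expect_equal(net$A[1, 2], 1)
  expect_equal(net$A[1, 1], 1)
})

test_that("hierarchy propagation sets every ancestor and is idempotent", {
  lh <- default_label_hierarchy()
  uni <- toy_universe(3)
  m <- matrix(0, 3, length(lh$label_names),
              dimnames = list(uni$ids, lh$label_names))
  m["g1", "Brain.Alzheimer"] <- 1
  m["g3", "Disease.Respiratory.Asthma"] <- 1 # childless secondary
  lab <- propagate_hierarchy(label_matrix(m, uni, lh$label_names, lh$hierarchy))
  expect_equal(lab$matrix["g1", "Disease.Brain"], 1)
  expect_equal(lab$matrix["g1", "Class_Disease"], 1)
  expect_equal(sum(lab$matrix["g2", ]), 0) # all-zero row untouched
  expect_equal(lab$matrix["g3", "Class_Disease"], 1)
  expect_equal(sum(lab$matrix["g3", ]), 2) # only the primary is added
  expect_identical(propagate_hierarchy(lab)$matrix, lab$matrix)
})

test_that("propagation is idempotent on randomly annotated matrices", {
  lh <- default_label_hierarchy()
  for (seed in 1:5) {
    set.seed(seed)
    uni <- toy_universe(12)
    m <- matrix(rbinom(12 * 27, 1, 0.15), 12, 27,
                dimnames = list(uni$ids, lh$label_names))
    lab <- propagate_hierarchy(label_matrix(m, uni, lh$label_names, lh$hierarchy))
    expect_identical(propagate_hierarchy(lab)$matrix, lab$matrix)
    # child positive implies parent positive
    for (ch in names(lh$hierarchy)) {
      parent <- lh$hierarchy[[ch]]
      expect_true(all(lab$matrix[, parent] >= lab$matrix[, ch]))
    }
  }
})

test_that("cyclic or multi-root hierarchies are rejected", {
  uni <- toy_universe(2)
  m <- matrix(0, 2, 3, dimnames = list(uni$ids, c("a", "b", "c")))
  expect_error(label_matrix(m, uni, c("a", "b", "c"),
                            c(a = "b", b = "a")), "cycle|root")
  expect_error(label_matrix(m, uni, c("a", "b", "c"),
                            c(a = "b", c = "b", b = "a")), "cycle")
})

test_that("alignment strategies handle unknown genes as documented", {
  uni <- toy_universe(3)
  d1 <- feature_dataset("d1", matrix(1, 3, 2), uni, "boolean",
                        known_mask = c(TRUE, TRUE, FALSE))
  d2 <- feature_dataset("d2", matrix(0.5, 3, 2), uni, "continuous")
  lab <- label_matrix(matrix(1, 3, 1, dimnames = list(NULL, "L")), uni, "L")

  ex <- align_datasets(list(d1, d2), lab, "exclude")
  expect_equal(length(ex$universe), 2)
  expect_true(all(vapply(ex$datasets, function(d) nrow(d$matrix), integer(1)) == 2))
  expect_equal(nrow(ex$labels$matrix), 2)

  inc <- align_datasets(list(d1, d2), lab, "include")
  expect_equal(length(inc$universe), 3)
  expect_equal(unname(inc$datasets[[1]]$matrix[3, ]), c(0, 0)) # zero-imputed

  # no unknowns: both strategies identical
  d1b <- feature_dataset("d1", matrix(1, 3, 2), uni, "boolean")
  ex2 <- align_datasets(list(d1b, d2), lab, "exclude")
  inc2 <- align_datasets(list(d1b, d2), lab, "include")
  expect_identical(ex2$datasets[[1]]$matrix, inc2$datasets[[1]]$matrix)

  # exclusion removing all genes is an error
  d_none <- feature_dataset("none", matrix(0, 3, 1), uni, "boolean",
                            known_mask = rep(FALSE, 3))
  expect_error(align_datasets(list(d_none), lab, "exclude"), "every gene")

  expect_lte(length(ex$universe), length(inc$universe))
})

test_that("feature and label tables round-trip exactly through TSV", {
  uni <- toy_universe(4)
  set.seed(7)
  m <- matrix(round(rnorm(12), 6), 4, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  d <- feature_dataset("expr", m, uni, "continuous",
                       known_mask = c(TRUE, FALSE, TRUE, TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(d, f)
  d2 <- read_feature_table(f, uni, name = "expr", kind = "continuous")
  expect_equal(d2$matrix, d$matrix)
  expect_equal(d2$known_mask, d$known_mask)

  lh <- list(label_names = c("root", "x", "y"),
             hierarchy = c(x = "root", y = "root"))
  lm <- matrix(rbinom(12, 1, 0.4), 4, 3, dimnames = list(NULL, lh$label_names))
  lab <- label_matrix(lm, uni, lh$label_names, lh$hierarchy)
  fl <- withr::local_tempfile(fileext = ".tsv")
  fh <- withr::local_tempfile(fileext = ".tsv")
  write_label_table(lab, fl, fh)
  lab2 <- read_label_table(fl, uni, fh)
  expect_equal(lab2$matrix, lab$matrix)
  expect_equal(lab2$hierarchy, lab$hierarchy)

  net <- random_network(6, seed = 3)
  fe <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, fe)
  net2 <- load_edge_list(fe, net$universe)
  expect_equal(net2$A, net$A, tolerance = 1e-12)
})

test_that("unknown proportion is reported per dataset", {
  uni <- toy_universe(10)
  d <- feature_dataset("d", matrix(0, 10, 1), uni, "boolean",
                       known_mask = c(rep(TRUE, 8), FALSE, FALSE))
  expect_equal(unknown_proportion(d), 0.2)
})

test_that("pipeline config validates and round-trips through YAML", {
  cfg <- benchmark_config(seeds = 1:5)
  expect_error(pipeline_config(restart_prob = 0), "restart_prob")
  expect_error(pipeline_config(seeds = 1:3, min_frequency = 10))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, f)
  cfg2 <- read_pipeline_config(f)
  expect_equal(cfg2$seeds, cfg$seeds)
  expect_equal(cfg2$encoder1$layer_sizes, cfg$encoder1$layer_sizes)
  expect_equal(cfg2$encoder1$learning_rate, cfg$encoder1$learning_rate)
  expect_equal(cfg2$strategy, cfg$strategy)
})
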