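test_that("transition matrix is the column-normalised adjacency", {
  uni2 <- toy_universe(2)
  tm <- build_transition_matrix(weighted_network(matrix(c(0, 1, 1, 0), 2), uni2))
  expect_equal(unname(tm$B), matrix(c(0, 1, 1, 0), 2))

  A <- matrix(c(0, 2, 1, 2, 0, 0, 1, 0, 0), 3) # column sums 3, 2, 1
  tm <- build_transition_matrix(weighted_network(A, toy_universe(3)))
  expect_equal(unname(tm$B),
               matrix(c(0, 2 / 3, 1 / 3, 1, 0, 0, 1, 0, 0), 3))

  # isolated nodes get a self-loop, keeping B stochastic
  tm <- build_transition_matrix(weighted_network(matrix(0, 2, 2), uni2))
  expect_equal(unname(tm$B), diag(2))
})

test_that("transition columns always sum to one", {
  for (seed in 1:10) {
    net <- random_network(sample(3:15, 1), seed = seed)
    tm <- build_transition_matrix(net)
    expect_true(all(abs(colSums(tm$B) - 1) < 1e-10))
    expect_true(all(tm$B >= 0))
  }
})

test_that("rwr fixed point matches hand-derived cases", {
  uni1 <- gene_universe("g1")
  tm1 <- build_transition_matrix(weighted_network(matrix(1, 1, 1), uni1))
  expect_equal(unname(rwr(tm1, 1, 0.7)), 1)

  net <- weighted_network(matrix(c(0, 1, 1, 0), 2), toy_universe(2))
  tm <- build_transition_matrix(net)
  expect_equal(unname(rwr(tm, 1, restart_prob = 1)), c(1, 0)) # instant restart
  expect_equal(unname(rwr(tm, 1, 0.5)), c(2 / 3, 1 / 3), tolerance = 1e-8)
  expect_equal(unname(rwr(tm, 1, 0.5, method = "solve")), c(2 / 3, 1 / 3))
})

test_that("rwr reports non-convergence with the residual", {
  net <- ring_network(6)
  tm <- build_transition_matrix(net)
  expect_error(rwr(tm, 1, 0.1, tol = 1e-14, max_iter = 2), "did not converge")
})

test_that("power iteration agrees with the closed-form solve on random graphs", {
  worst <- 0
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(2:20, 1)
    net <- random_network(n, p = runif(1, 0.2, 0.8), seed = seed + 1000)
    tm <- build_transition_matrix(net)
    i <- sample(n, 1)
    p_r <- runif(1, 0.1, 0.9)
    dev <- max(abs(rwr(tm, i, p_r, tol = 1e-12) -
                   rwr(tm, i, p_r, method = "solve")))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-8)
})

test_that("diffusion states conserve probability and localise around the seed", {
  net <- weighted_network(matrix(c(0, 1, 1, 0), 2), toy_universe(2))
  ds <- compute_diffusion_states(net, 0.5)
  expect_equal(unname(ds$S), matrix(c(2 / 3, 1 / 3, 1 / 3, 2 / 3), 2),
               tolerance = 1e-10)
  expect_equal(unname(compute_diffusion_states(net, 1)$S), diag(2))

  # conservation on random networks, both dense and power-iteration paths
  for (seed in 1:5) {
    net <- random_network(12, seed = seed)
    S1 <- compute_diffusion_states(net, 0.5)$S
    S2 <- compute_diffusion_states(net, 0.5, solve_limit = 0)$S
    expect_true(all(abs(colSums(S1) - 1) < 1e-8))
    expect_true(all(S1 >= -1e-12))
    expect_equal(S1, S2, tolerance = 1e-7)
  }

  # monotone locality on a path graph: the seed is its own most-visited node
  n <- 7
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) { A[i, i + 1] <- 1; A[i + 1, i] <- 1 }
  S <- compute_diffusion_states(weighted_network(A, toy_universe(n)), 0.4)$S
  for (i in seq_len(n)) expect_true(all(S[i, i] > S[-i, i]))
})

test_that("annotation similarity networks use cosine of annotation rows", {
  uni <- toy_universe(3)
  M <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1))
  d <- feature_dataset("go", M, uni, "boolean")
  net <- annotation_to_network(d, similarity_threshold = 0)
  expect_equal(net$A[1, 2], 1 / sqrt(2))
  expect_equal(net$A[1, 3], 0) # orthogonal rows
  expect_equal(diag(net$A), setNames(rep(0, 3), uni$ids))

  ident <- feature_dataset("go", rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1)), uni, "boolean")
  expect_equal(annotation_to_network(ident)$A[1, 2], 1)

  thr <- annotation_to_network(d, similarity_threshold = 0.9)
  expect_equal(thr$A[1, 2], 0)

  zero <- feature_dataset("z", matrix(0, 3, 2), uni, "boolean")
  expect_warning(annotation_to_network(zero), "empty")
})

test_that("full-rank svd embedding reconstructs the log-diffusion matrix", {
  net <- random_network(8, seed = 11)
  ds <- compute_diffusion_states(net, 0.5)
  emb <- mashup_embed(net, d = 8, restart_prob = 0.5)
  L <- log(ds$S + 1 / 8)
  expect_lt(max(abs(L - emb$contexts[[1]] %*% t(emb$X))), 1e-6)
})

test_that("duplicated networks embed with the same distance structure as one", {
  net <- random_network(10, seed = 21)
  e1 <- mashup_embed(net, d = 4)
  e2 <- mashup_embed(list(net, net), d = 4)
  d1 <- as.vector(dist(e1$X))
  d2 <- as.vector(dist(e2$X))
  expect_equal(order(d1), order(d2))
  expect_equal(cor(d1, d2), 1, tolerance = 1e-8)
})

test_that("infeasible embedding dimension is reduced with a warning", {
  net <- random_network(5, seed = 2)
  expect_warning(emb <- mashup_embed(net, d = 12), "reduced")
  expect_equal(emb$d, 5)
})

test_that("softmax embedding reduces KL against the diffusion columns", {
  net <- random_network(8, seed = 31)
  ds <- compute_diffusion_states(net, 0.5)
  kl <- function(X, W) {
    Z <- W %*% t(X)
    P <- apply(Z, 2, function(z) { e <- exp(z - max(z)); e / sum(e) })
    mean(colSums(ds$S * log(pmax(ds$S, 1e-12) / P)))
  }
  set.seed(5)
  X0 <- matrix(rnorm(8 * 3, sd = 0.1), 8, 3)
  W0 <- matrix(rnorm(8 * 3, sd = 0.1), 8, 3)
  emb <- mashup_embed(net, d = 3, method = "softmax", seed = 5, n_iter = 300)
  expect_lt(kl(emb$X, emb$contexts[[1]]), kl(X0, W0))
})

test_that("embedding reduction percentage follows the defining formula", {
  expect_equal(round(reduction_percentage(15000, 800)), 95)
  expect_equal(reduction_percentage(15000, 800), (1 - 800 / 15000) * 100)
  expect_equal(reduction_percentage(100, 100), 0)
  expect_equal(reduction_percentage(200, 50), 75)
  expect_warning(out <- reduction_percentage(100, 150), "exceeds")
  expect_lt(out, 0)
})
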