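test_that("closed-form values on canonical small graphs", {
  K5 <- 1 - diag(5)
  nm <- compute_node_metrics(K5)
  expect_equal(nm$degree, rep(4, 5))
  expect_equal(nm$clustering, rep(1, 5))
  expect_equal(nm$eglob, rep(1, 5))
  expect_equal(nm$eloc, rep(1, 5))
  g <- compute_global_metrics(K5)
  expect_equal(g$cbar, 1)
  expect_equal(g$L, 1)
  expect_false(g$disconnected)

  # star with 4 leaves: centre k=4 C=0; leaves reach centre in 1, others in 2
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  nm <- compute_node_metrics(star)
  expect_equal(nm$degree[1], 4)
  expect_equal(nm$clustering[1], 0)
  expect_equal(nm$eglob[2], (1 + 3 * 0.5) / 4)  # 0.625
  expect_equal(nm$eloc, rep(0, 5))  # centre's neighbours are disconnected

  # 5-cycle: no triangles, distances 1,1,2,2 from each node
  C5 <- ring_lattice(5, 1)
  g <- compute_global_metrics(C5)
  expect_equal(g$cbar, 0)
  expect_equal(g$L, 1.5)

  # two disjoint triangles: disconnected flag, within-component L = 1
  tt <- matrix(0, 6, 6)
  tt[1:3, 1:3] <- 1 - diag(3)
  tt[4:6, 4:6] <- 1 - diag(3)
  g <- compute_global_metrics(tt)
  expect_true(g$disconnected)
  expect_equal(g$L, 1)

  expect_error(compute_global_metrics(matrix(0, 4, 4)), "edgeless")
  expect_error(compute_node_metrics(matrix(2, 3, 3)), "binary")
})

test_that("metrics agree with brute-force oracles on seeded graphs up to 12 nodes", {
  worst <- 0
  n_graphs <- 0
  for (n in 5:12) for (p in c(0.2, 0.4, 0.7)) for (r in 1:5) {
    A <- random_graph(n, p, seed = 1000 * n + 100 * p * 10 + r)
    if (sum(A) == 0) next
    n_graphs <- n_graphs + 1
    nm <- compute_node_metrics(A)
    bf <- bf_node_metrics(A)
    for (m in c("degree", "clustering", "eglob", "eloc"))
      worst <- max(worst, max(abs(nm[[m]] - bf[[m]])))
    g <- compute_global_metrics(A)
    bg <- bf_global_metrics(A)
    worst <- max(worst, abs(g$cbar - bg$cbar), abs(g$L - bg$L))
    expect_identical(g$disconnected, bg$disconnected)
  }
  expect_gte(n_graphs, 100)
  expect_lt(worst, 1e-12)
})

test_that("metric ranges and degree-sum identity hold on random graphs", {
  for (r in 1:20) {
    A <- random_graph(10, runif(1, 0.2, 0.8), seed = 500 + r)
    nm <- compute_node_metrics(A)
    expect_equal(sum(nm$degree), sum(A))  # sum k_i = 2 x edges
    expect_true(all(nm$clustering >= 0 & nm$clustering <= 1))
    expect_true(all(nm$eglob >= 0 & nm$eglob <= 1))
    expect_true(all(nm$eloc >= 0 & nm$eloc <= 1))
  }
})

test_that("nodal global efficiency never decreases when an edge is added", {
  set.seed(99)
  for (r in 1:15) {
    A <- random_graph(9, 0.35, seed = 700 + r)
    empty <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(empty) == 0) next
    pick <- empty[sample(nrow(empty), 1), ]
    B <- A
    B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- 1
    e0 <- compute_node_metrics(A, metrics = "eglob")$eglob
    e1 <- compute_node_metrics(B, metrics = "eglob")$eglob
    expect_true(all(e1 - e0 >= -1e-15))
  }
})

test_that("rewiring preserves the degree sequence and is seed-deterministic", {
  A <- random_graph(20, 0.3, seed = 3)
  B1 <- rewire_null(A, rng_seed = 7)
  B2 <- rewire_null(A, rng_seed = 7)
  B3 <- rewire_null(A, rng_seed = 8)
  expect_identical(B1, B2)
  expect_false(identical(unname(B1), unname(B3)))
  expect_equal(rowSums(B1), rowSums(A))
  expect_equal(sum(B1), sum(A))
  expect_true(all(diag(B1) == 0))
  expect_true(all(B1 %in% c(0, 1)))

  # complete graph admits no swap: comes back unchanged and flagged
  K5 <- 1 - diag(5)
  out <- rewire_null(K5, rng_seed = 1)
  expect_equal(unname(out), unname(K5), ignore_attr = TRUE)
  expect_true(isTRUE(attr(out, "no_swap")))

  expect_error(rewire_null(matrix(0, 3, 3), 1), "2 edges")
})

test_that("small-world indices behave as expected on reference graphs", {
  # complete graph: nulls are identical, so gamma = lambda = sigma = 1
  K5 <- 1 - diag(5)
  sw <- compute_small_world(K5, n_null = 5, rng_seed = 1)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)

  # an already-random dense graph: indices ~ 1
  A <- random_graph(34, 224 / 561, seed = 10)
  sw <- compute_small_world(A, n_null = 30, rng_seed = 2)
  expect_equal(sw$gamma, 1, tolerance = 0.1)
  expect_equal(sw$lambda, 1, tolerance = 0.05)
  expect_equal(sw$sigma, 1, tolerance = 0.12)
  expect_identical(sw$sigma, sw$gamma / sw$lambda)  # bit-exact ratio

  # ring lattice: high clustering, so gamma >> 1 and sigma > 1
  L <- ring_lattice(34, 4)
  sw <- compute_small_world(L, n_null = 20, rng_seed = 3)
  expect_gt(sw$gamma, 1.5)
  expect_gt(sw$sigma, 1)
})

test_that("metric panel is rectangular, sane, and exports long tables", {
  coh <- make_fixture("tiny")
  cfg <- hemisnet_config(n_null_networks = 3)
  nets <- build_networks(coh, cfg)
  mp <- compute_metric_panel(nets, cfg)
  expect_equal(dim(mp$node), c(12, 34, 4, 2))
  expect_equal(dim(mp$hemi), c(12, 3, 2))
  expect_identical(mp$hemi[, "sigma", ],
                   mp$hemi[, "gamma", ] / mp$hemi[, "lambda", ])
  tab <- metrics_to_table(mp)
  expect_equal(nrow(tab), 12 * 34 * 4 * 2 + 12 * 3 * 2)
  expect_true(all(tab$value[tab$metric == "degree"] %% 1 == 0))
})
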