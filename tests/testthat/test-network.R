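test_that("control reference reproduces hand-computed mean and sample SD", {
  coh <- make_fixture("tiny")
  sub <- coh$subjects
  th <- coh$thickness
  # plant known control values in one dataset/region
  ctrl <- which(sub$diagnosis == "control" & sub$dataset_id == "ds01")
  th[ctrl, "bankssts_L"] <- c(2.0, 2.5, 3.0)
  coh2 <- hemisnet_cohort(th, sub)
  ref <- compute_control_reference(coh2)
  expect_equal(ref$mean["ds01", "bankssts_L"], 2.5)
  expect_equal(ref$sd["ds01", "bankssts_L"], 0.5)  # sample SD, n-1

  # perturbing cases does not move the reference
  th3 <- th
  cases <- sub$diagnosis == "case"
  th3[cases, ] <- th3[cases, ] + 5
  ref3 <- compute_control_reference(hemisnet_cohort(th3, sub))
  expect_identical(ref3$mean, ref$mean)
  expect_identical(ref3$sd, ref$sd)

  # identical controls in a region -> SD 0 -> error naming both culprits
  th4 <- th
  th4[ctrl, "cuneus_R"] <- 2.2
  expect_error(compute_control_reference(hemisnet_cohort(th4, sub)),
               "ds01.*cuneus_R")
})

test_that("standardization is the controls-referenced z-score", {
  coh <- make_fixture("tiny")
  ref <- compute_control_reference(coh)
  z <- standardize(coh, ref)
  # direct formula spot check
  expect_equal(z[1, "fusiform_L"],
               (coh$thickness[1, "fusiform_L"] -
                  ref$mean["ds01", "fusiform_L"]) /
                 ref$sd["ds01", "fusiform_L"])
  # controls of each dataset have mean 0 / sample SD 1 per region
  for (d in c("ds01", "ds02")) {
    sel <- coh$subjects$diagnosis == "control" & coh$subjects$dataset_id == d
    expect_equal(max(abs(colMeans(z[sel, ]))), 0, tolerance = 1e-12)
    expect_equal(max(abs(apply(z[sel, ], 2, sd) - 1)), 0, tolerance = 1e-12)
  }
  # cases need not be centred
  cases <- coh$subjects$diagnosis == "case"
  expect_gt(max(abs(colMeans(z[cases, ]))), 1e-3)
})

test_that("weighted network is the Gaussian similarity kernel", {
  z <- c(0, 2, rnorm(32))
  names(z) <- dk_regions()
  w <- build_weighted_network(z)
  expect_equal(w[1, 2], exp(-2))        # |dz| = 2
  expect_equal(diag(w), setNames(rep(0, 34), dk_regions()))
  expect_identical(w, t(w))
  z2 <- z; z2[5] <- z2[4]
  expect_equal(build_weighted_network(z2)[4, 5], 1)  # equal z -> w = 1
  expect_error(build_weighted_network(c(z[-1], NA)), "non-finite")

  # permutation equivariance
  perm <- sample(34)
  wp <- build_weighted_network(z[perm])
  expect_equal(unname(wp), unname(w[perm, perm]))
})

test_that("sparsity thresholding retains exactly floor(S * n_pairs) edges", {
  set.seed(1)
  z <- rnorm(34)
  w <- build_weighted_network(z)
  b <- binarize_by_sparsity(w, 0.4)
  expect_equal(sum(b[upper.tri(b)]), 224)  # 0.4 of 561
  expect_identical(b, t(b))
  expect_true(all(b %in% c(0, 1)))

  # exhaustive check on a 5-node toy: the 4 strongest of 10 pairs survive
  w5 <- matrix(0, 5, 5)
  vals <- seq(0.9, 0, length.out = 10)
  w5[upper.tri(w5)] <- sample(vals)
  w5 <- w5 + t(w5)
  b5 <- binarize_by_sparsity(w5, 0.4)
  expect_equal(sum(b5[upper.tri(b5)]), 4)
  kept <- w5[upper.tri(w5)][b5[upper.tri(b5)] == 1]
  expect_setequal(kept, sort(w5[upper.tri(w5)], decreasing = TRUE)[1:4])

  # all-equal weights: still m edges, chosen by the deterministic tie order
  weq <- matrix(0.5, 5, 5); diag(weq) <- 0
  beq1 <- binarize_by_sparsity(weq, 0.4)
  beq2 <- binarize_by_sparsity(weq, 0.4)
  expect_identical(beq1, beq2)
  expect_equal(sum(beq1[upper.tri(beq1)]), 4)

  expect_error(binarize_by_sparsity(w, 0), "sparsity")
  expect_error(binarize_by_sparsity(w, 1.1), "sparsity")
})

test_that("edge count is conserved for every subject/hemisphere/threshold", {
  coh <- make_fixture("tiny")
  nets <- build_networks(coh, hemisnet_config())
  for (s in c(0.25, 0.4, 0.5)) {
    m <- floor(s * 561)
    for (k in c(1, 7)) for (h in 1:2) {
      b <- binarize_by_sparsity(nets$weighted[k, , , h], s)
      expect_equal(sum(b) / 2, m)
    }
  }
})

test_that("binary networks are invariant to monotone kernel changes", {
  set.seed(42)
  for (rep in 1:10) {
    z <- rnorm(34)
    gauss <- build_weighted_network(z)
    # a different strictly decreasing function of |dz|
    alt <- 1 / (1 + abs(outer(z, z, "-")))
    diag(alt) <- 0
    for (s in c(0.25, 0.4, 0.5))
      expect_identical(binarize_by_sparsity(gauss, s),
                       binarize_by_sparsity(alt, s))
  }
})

test_that("construction treats the hemispheres symmetrically", {
  coh <- make_fixture("tiny")
  nets <- build_networks(coh, hemisnet_config())
  nets_sw <- build_networks(swap_hemispheres(coh), hemisnet_config())
  expect_equal(nets_sw$weighted[, , , "L"], nets$weighted[, , , "R"])
  expect_equal(nets_sw$binary[, , , "R"], nets$binary[, , , "L"])
})
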