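test_that("trapezoid AUC reproduces closed forms and is linear", {
  s <- seq(0.25, 0.50, by = 0.01)
  # constant metric m over width 0.25
  expect_equal(auc_trapezoid(s, rep(3, 26)), 3 * 0.25)
  # linear from a at 0.25 to b at 0.50
  a <- 1.2; b <- 4.8
  y <- a + (b - a) * (s - 0.25) / 0.25
  expect_equal(auc_trapezoid(s, y), 0.25 * (a + b) / 2)
  # linearity in the metric
  set.seed(6)
  v <- runif(26)
  expect_equal(auc_trapezoid(s, 7 * v), 7 * auc_trapezoid(s, v))
  # matrix form matches the vector form row-wise
  M <- rbind(y, v)
  expect_equal(auc_trapezoid(s, M),
               c(auc_trapezoid(s, y), auc_trapezoid(s, v)))
  expect_error(auc_trapezoid(c(0.3, 0.25), c(1, 2)), "increasing")
})

test_that("edge sets are nested across the sparsity sweep", {
  coh <- make_fixture("tiny")
  nets <- build_networks(coh, hemisnet_config())
  sv <- seq(0.25, 0.50, by = 0.05)
  for (k in c(2, 9)) for (h in 1:2) {
    prev <- NULL
    for (s in sv) {
      b <- binarize_by_sparsity(nets$weighted[k, , , h], s)
      if (!is.null(prev))
        expect_true(all(b[prev == 1] == 1))  # larger S keeps all earlier edges
      prev <- b
    }
  }
})

test_that("sparsity sweep integrates curves and tests AUC-HDs", {
  coh <- make_fixture("tiny")
  cfg <- hemisnet_config(sparsity_range = seq(0.25, 0.50, by = 0.05),
                         n_permutations = 49, rng_seed = 2)
  sw <- quiet(run_sparsity_sweep(coh, cfg, node_metrics = "degree"))
  expect_s3_class(sw, "hemisnet_sweep")
  expect_equal(dim(sw$values), c(12, 34, 1, 2, 6))
  # AUC recomputable from the stored curves
  expect_equal(sw$auc[3, 5, "degree", "L"],
               auc_trapezoid(sw$thresholds, sw$values[3, 5, "degree", "L", ]))
  # HD-of-AUC equals AUC-of-HD (both linear)
  hd_curve <- sw$values[4, 8, "degree", "L", ] -
    sw$values[4, 8, "degree", "R", ]
  expect_equal(sw$auc[4, 8, "degree", "L"] - sw$auc[4, 8, "degree", "R"],
               auc_trapezoid(sw$thresholds, hd_curve))
  expect_equal(nrow(sw$results), 34)
  tab <- sweep_to_table(sw)
  expect_equal(nrow(tab), 12 * 34 * 1 * 2 * 6)
})

test_that("the injected effect survives the sparsity sweep with the same sign", {
  coh <- make_fixture("effect")
  # n_perm >= 2720 so a node-tier BH discovery is reachable (see above)
  cfg <- hemisnet_config(sparsity_range = seq(0.25, 0.50, by = 0.05),
                         n_permutations = 3000, rng_seed = 29)
  sw <- quiet(run_sparsity_sweep(coh, cfg, node_metrics = "degree"))
  fus <- sw$results[sw$results$node == "fusiform", ]
  main <- quiet(run_node_level_analysis(coh,
                                        hemisnet_config(n_permutations = 3000,
                                                        rng_seed = 29),
                                        node_metrics = "degree",
                                        hemisphere = FALSE))
  fus_main <- main[main$tier == "node" & main$node == "fusiform", ]
  expect_equal(sign(fus$cohens_d), sign(fus_main$cohens_d))
  expect_lt(fus$cohens_d, 0)
  expect_true(fus$significant)
})

test_that("model variants preserve conclusions under their null conditions", {
  coh <- make_fixture("tiny")
  cfg <- hemisnet_config(n_permutations = 99, rng_seed = 3)
  nets <- build_networks(coh, cfg)
  mp <- compute_metric_panel(nets, cfg, node_metrics = "degree",
                             hemisphere = FALSE)
  # with a purely linear age effect, the quadratic-age variant recovers
  # essentially the same diagnosis coefficient
  nul <- make_fixture("null")
  set.seed(77)
  y <- 0.5 * (nul$subjects$diagnosis == "case") -
    0.02 * nul$subjects$age + rnorm(nrow(nul$subjects), sd = 0.3)
  f_main <- quiet(fit_case_control_model(y, nul$subjects))
  f_quad <- quiet(fit_case_control_model(y, nul$subjects,
                                         variant = "nonlinear_age"))
  expect_equal(f_quad$coefficient, f_main$coefficient, tolerance = 0.1)

  # adding a constant to every region changes the global-thickness
  # covariate but not a single HD conclusion
  coh2 <- hemisnet_cohort(coh$thickness + 0.5, coh$subjects)
  vg <- quiet(run_node_level_analysis(coh, cfg, "degree", FALSE,
                                      NULL, NULL,
                                      variant = "global_thickness"))
  vg2 <- quiet(run_node_level_analysis(coh2, cfg, "degree", FALSE,
                                       NULL, NULL,
                                       variant = "global_thickness"))
  expect_equal(vg2$coefficient, vg$coefficient, tolerance = 1e-6)
  expect_identical(vg2$significant, vg$significant)

  # run_model_variants stacks both variants
  rv <- quiet(run_model_variants(coh, cfg, node_metrics = "degree",
                                 hemisphere = FALSE, networks = nets,
                                 metrics = mp))
  expect_setequal(unique(rv$variant),
                  c("nonlinear_age", "global_thickness"))
  expect_equal(sum(rv$tier == "node"), 2 * 34)
})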