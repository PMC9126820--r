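test_that("hemispheric difference is Left minus Right and antisymmetric", {
  expect_equal(compute_hd(10, 7), 3)
  expect_equal(compute_hd(4.2, 4.2), 0)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(compute_hd(a, b), -compute_hd(b, a))
  expect_true(is.na(compute_hd(Inf, 1)))
  expect_true(is.na(compute_hd(1, NA)))
})

test_that("mixed model recovers exact and invariant structure", {
  coh <- make_fixture("null")
  sub <- coh$subjects

  # noise-free group difference is recovered exactly
  y <- ifelse(sub$diagnosis == "case", 0.5, 0.0)
  f <- quiet(fit_case_control_model(y, sub))
  expect_equal(f$coefficient, 0.5, tolerance = 1e-9)

  # a per-dataset constant shift is absorbed by the random intercept
  y2 <- rnorm(nrow(sub), sd = 0.3)
  f0 <- quiet(fit_case_control_model(y2, sub))
  shift <- c(ds01 = 5, ds02 = -3, ds03 = 11, ds04 = 0.5, ds05 = -7)
  f1 <- quiet(fit_case_control_model(y2 + shift[sub$dataset_id], sub))
  expect_lt(abs(f1$coefficient - f0$coefficient), 0.02)

  # degenerate designs error informatively
  expect_error(quiet(fit_case_control_model(rep(1, nrow(sub)), sub)),
               "constant")
  one_ds <- sub$dataset_id == "ds01"
  expect_error(quiet(fit_case_control_model(y2[one_ds], sub[one_ds, ])),
               "2 datasets")
  ctrl <- sub$diagnosis == "control"
  expect_error(quiet(fit_case_control_model(y2[ctrl], sub[ctrl, ])),
               "both diagnosis groups")
})

test_that("REML estimates match lme4 across outcomes and variants", {
  skip_if_not_installed("lme4")
  coh <- make_fixture("null")
  sub <- coh$subjects
  df <- data.frame(diag = as.numeric(sub$diagnosis == "case"),
                   age = sub$age, sexM = as.numeric(sub$sex == "M"),
                   ds = sub$dataset_id,
                   gt = rowMeans(coh$thickness))
  set.seed(31)
  for (r in 1:5) {
    df$y <- 0.1 * df$diag + rnorm(nrow(df), sd = runif(1, 0.1, 2)) +
      rep(rnorm(5, sd = runif(1, 0, 1)), table(sub$dataset_id))
    ours <- quiet(fit_case_control_model(df$y, sub))
    m <- lme4::lmer(y ~ diag + age + sexM + (1 | ds), data = df,
                    REML = TRUE)
    cs <- lme4::fixef(m)
    expect_equal(ours$coefficient, unname(cs["diag"]), tolerance = 1e-6)
    expect_equal(ours$t, coef(summary(m))["diag", "t value"],
                 tolerance = 1e-5)
  }
  # quadratic-age variant
  ours <- quiet(fit_case_control_model(df$y, sub, variant = "nonlinear_age"))
  df$age2 <- (df$age - mean(df$age))^2
  m <- lme4::lmer(y ~ diag + age + sexM + age2 + (1 | ds), df, REML = TRUE)
  expect_equal(ours$t, coef(summary(m))["diag", "t value"],
               tolerance = 1e-5)
  # global-thickness variant
  ours <- quiet(fit_case_control_model(df$y, sub,
                                       variant = "global_thickness",
                                       global_thickness = df$gt))
  m <- lme4::lmer(y ~ diag + age + sexM + gt + (1 | ds), df, REML = TRUE)
  expect_equal(ours$t, coef(summary(m))["diag", "t value"],
               tolerance = 1e-5)
})

test_that("Cohen's d conversion follows the two-group t formula", {
  expect_equal(cohens_d_from_t(0, 10, 12, 20), 0)
  expect_equal(cohens_d_from_t(2, 50, 50, 96), 2 * 100 / (50 * sqrt(96)))
  set.seed(4)
  t <- rnorm(50)
  expect_equal(sign(cohens_d_from_t(t, 13, 17, 28)), sign(t))
  expect_error(cohens_d_from_t(1, 10, 10, 0), "df")
})

test_that("permutation p-values are deterministic, bounded and floor-limited", {
  coh <- make_fixture("null")
  sub <- coh$subjects
  set.seed(8)
  y <- rnorm(nrow(sub))
  p1 <- quiet(permutation_pvalue(y, sub, n_perm = 199, rng_seed = 5))
  p2 <- quiet(permutation_pvalue(y, sub, n_perm = 199, rng_seed = 5))
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_gte(as.numeric(p1), 1 / 200)
  expect_lte(as.numeric(p1), 1)

  # an overwhelming effect hits the add-one floor
  y3 <- ifelse(sub$diagnosis == "case", 10, 0) + rnorm(nrow(sub), sd = 0.1)
  p3 <- quiet(permutation_pvalue(y3, sub, n_perm = 200, rng_seed = 2))
  expect_equal(as.numeric(p3), 1 / 201)
})

test_that("permutation p converges to the exact label-exchange p on a tiny cohort", {
  # 8 subjects, 2 datasets, 2 cases + 2 controls each: 36 arrangements
  sub <- data.frame(
    subject_id = sprintf("s%d", 1:8),
    dataset_id = rep(c("d1", "d2"), each = 4),
    diagnosis = rep(c("case", "case", "control", "control"), 2),
    age = c(10, 12, 11, 14, 9, 13, 15, 10),
    # three M / one F and one M / three F: no choice of 2 cases per
    # dataset can make diagnosis collinear with sex, so every label
    # arrangement is estimable
    sex = c("M", "M", "M", "F", "M", "F", "F", "F"),
    stringsAsFactors = FALSE)
  set.seed(21)
  y <- rnorm(8) + 0.8 * (sub$diagnosis == "case")

  swaps <- enumerate_label_swaps(sub)
  expect_equal(length(swaps), 36)
  tvals <- vapply(swaps, function(lab) {
    s2 <- sub; s2$diagnosis <- lab
    quiet(fit_case_control_model(y, s2))$t
  }, numeric(1))
  t_obs <- quiet(fit_case_control_model(y, sub))$t
  exact_p <- mean(abs(tvals) >= abs(t_obs) - 1e-10)

  p_hat <- quiet(permutation_pvalue(y, sub, n_perm = 3000, rng_seed = 11))
  expect_equal(as.numeric(p_hat), exact_p, tolerance = 0.04)
})

test_that("permutation p-values are uniform under the null", {
  coh <- make_fixture("null")
  sub <- coh$subjects
  set.seed(303)
  ps <- vapply(1:150, function(r) {
    y <- rnorm(nrow(sub)) + rep(rnorm(5, sd = 0.3), table(sub$dataset_id))
    as.numeric(quiet(permutation_pvalue(y, sub, n_perm = 199,
                                        rng_seed = 1000 + r)))
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.05)
})

test_that("tiered multiple-testing adjustment matches hand computations", {
  hemi <- adjust_pvalues(c(0.02, 0.10, 0.04), "hemisphere")
  expect_equal(hemi$significant, c(FALSE, FALSE, FALSE))  # 0.05/3 = 0.0167
  hemi2 <- adjust_pvalues(c(0.01, 0.10, 0.04), "hemisphere")
  expect_equal(hemi2$significant, c(TRUE, FALSE, FALSE))

  bh <- adjust_pvalues(c(0.001, 0.011, 0.02, 0.8), "edge")
  expect_equal(bh$p_adjusted, c(0.004, 0.022, 4 * 0.02 / 3, 0.8),
               tolerance = 1e-12)

  node <- adjust_pvalues(rep(1, 34), "node")
  expect_false(any(node$significant))

  # BH monotonicity: sorted raw p gives sorted adjusted p
  set.seed(2)
  p <- sort(runif(34))
  adj <- adjust_pvalues(p, "node")
  expect_true(!is.unsorted(adj$p_adjusted))

  uni <- adjust_pvalues(c(0.03, 0.2), "unilateral")
  expect_equal(uni$p_adjusted, c(0.03, 0.2))
  expect_equal(uni$significant, c(TRUE, FALSE))

  expect_error(adjust_pvalues(numeric(0), "node"), "empty")
  expect_error(adjust_pvalues(c(0.1, 0), "node"), "0, 1")
})

test_that("within-case models recover planted associations and skip missing data", {
  coh <- make_fixture("effect")
  cases <- coh$subjects$diagnosis == "case"
  set.seed(55)
  coh$subjects$ados_total[cases] <- round(runif(sum(cases), 5, 25))
  cfg <- hemisnet_config(n_permutations = 499, n_null_networks = 2,
                         rng_seed = 4)

  nets <- build_networks(coh, cfg)
  mp <- compute_metric_panel(nets, cfg, node_metrics = "degree",
                             hemisphere = FALSE)
  # plant an HD ~ ados association by overwriting the metric panel copy
  hd_true <- compute_hd(mp$node[, "fusiform", "degree", "L"],
                        mp$node[, "fusiform", "degree", "R"])
  mp$node[, "fusiform", "degree", "R"] <-
    mp$node[, "fusiform", "degree", "L"] -
    (0.4 * ifelse(is.na(coh$subjects$ados_total), 0,
                  coh$subjects$ados_total) + rnorm(length(hd_true)))
  targets <- data.frame(metric = "degree", node = "fusiform",
                        stringsAsFactors = FALSE)
  res <- quiet(run_within_case_models(coh, targets, "ados", cfg,
                                      metrics = mp))
  expect_equal(nrow(res), 1)
  expect_false(res$skipped)
  expect_gt(res$coefficient, 0.2)
  expect_lt(res$p_empirical, 0.05)

  # all-missing IQ -> skip record, not an error
  res_iq <- quiet(run_within_case_models(coh, targets, "iq", cfg,
                                         metrics = mp))
  expect_true(res_iq$skipped)
  expect_equal(nrow(res_iq), 1)

  # empty target list -> empty result
  expect_equal(nrow(quiet(run_within_case_models(
    coh, targets[0, ], "ados", cfg, metrics = mp))), 0)
})
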