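result_row <- function(tier, metric, node, res, j, d, padj, sig) {
  data.frame(
    tier = tier, metric = metric, node = node,
    n_cases = res$n_cases, n_controls = res$n_controls,
    coefficient = res$coefficient[j], t = res$t_obs[j], df = res$df,
    cohens_d = d, p_empirical = res$p[j], p_adjusted = padj,
    significant = sig, stringsAsFactors = FALSE)
}

#' Main case-control asymmetry analysis
#'
#' Runs the complete inference chain on a cohort: hemispheric differences
#' (Left - Right) of the 3 hemisphere-level and 4 x 34 node-level metrics,
#' the random-intercept mixed model per HD, Cohen's d from the diagnosis t,
#' label-swap permutation p-values, Bonferroni correction at the hemisphere
#' tier and per-metric BH-FDR at the node tier, plus unilateral (left-only /
#' right-only) follow-up models for every significant HD.
#'
#' @param cohort A [hemisnet_cohort()].
#' @param config A [hemisnet_config()].
#' @param node_metrics Node-level metrics to analyse (default all four).
#' @param hemisphere Include the hemisphere-level (gamma/lambda/sigma) tier;
#'   requires the null-model normalization. Default TRUE.
#' @param networks,metrics Optional precomputed [build_networks()] /
#'   [compute_metric_panel()] results (recomputed when NULL).
#' @param variant Model variant passed to the mixed model (`"main"`,
#'   `"nonlinear_age"` or `"global_thickness"`).
#' @return Data frame of test results, one row per metric/node (tiers
#'   `"hemisphere"` and `"node"`, 3 + 34 x length(node_metrics) rows)
#'   followed by `"unilateral"` follow-up rows for significant HDs.
#'   Columns: tier, metric, node, n_cases, n_controls, coefficient, t, df,
#'   cohens_d, p_empirical, p_adjusted, significant.
#' @export
run_node_level_analysis <- function(cohort, config = hemisnet_config(),
                                    node_metrics = NODE_METRICS,
                                    hemisphere = TRUE,
                                    networks = NULL, metrics = NULL,
                                    variant = "main") {
  stopifnot(inherits(cohort, "hemisnet_cohort"))
  if (is.null(networks)) networks <- build_networks(cohort, config)
  if (is.null(metrics))
    metrics <- compute_metric_panel(networks, config,
                                    node_metrics = node_metrics,
                                    hemisphere = hemisphere)
  gthick <- if (identical(variant, "global_thickness"))
    rowMeans(cohort$thickness) else NULL
  out <- list()

  if (hemisphere && !is.null(metrics$hemi)) {
    Y <- compute_hd(metrics$hemi[, , "L"], metrics$hemi[, , "R"])
    res <- lmm_permutation_test(Y, cohort$subjects, variant,
                                config$n_permutations, config$rng_seed,
                                gthick,
                                global_permutation = config$global_permutation)
    d <- cohens_d_from_t(res$t_obs, res$n_cases, res$n_controls, res$df)
    adj <- adjust_pvalues(res$p, "hemisphere",
                          alpha = config$alpha_hemisphere)
    for (j in seq_len(ncol(Y)))
      out[[length(out) + 1L]] <- result_row(
        "hemisphere", HEMI_METRICS[j], NA_character_, res, j, d[j],
        adj$p_adjusted[j], adj$significant[j])
  }

  for (m in intersect(dimnames(metrics$node)[[3]], node_metrics)) {
    Y <- compute_hd(metrics$node[, , m, "L"], metrics$node[, , m, "R"])
    res <- lmm_permutation_test(Y, cohort$subjects, variant,
                                config$n_permutations, config$rng_seed,
                                gthick,
                                global_permutation = config$global_permutation)
    d <- cohens_d_from_t(res$t_obs, res$n_cases, res$n_controls, res$df)
    adj <- adjust_pvalues(res$p, "node", alpha = config$alpha_node)
    for (j in seq_len(ncol(Y)))
      out[[length(out) + 1L]] <- result_row(
        "node", m, dk_regions()[j], res, j, d[j],
        adj$p_adjusted[j], adj$significant[j])
  }
  main <- do.call(rbind, out)

  # unilateral follow-up of significant HDs: raw left and right outcomes
  uni <- list()
  sig <- main[main$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    for (side in c("L", "R")) {
      y <- if (sig$tier[i] == "hemisphere")
        metrics$hemi[, sig$metric[i], side]
      else metrics$node[, sig$node[i], sig$metric[i], side]
      res <- lmm_permutation_test(
        matrix(y, ncol = 1), cohort$subjects,
        if (side == "L") "unilateral_left" else "unilateral_right",
        config$n_permutations, config$rng_seed, NULL,
        global_permutation = config$global_permutation)
      d <- cohens_d_from_t(res$t_obs, res$n_cases, res$n_controls, res$df)
      adj <- adjust_pvalues(res$p, "unilateral")
      uni[[length(uni) + 1L]] <- result_row(
        paste0("unilateral_", side), sig$metric[i], sig$node[i],
        res, 1L, d, adj$p_adjusted, adj$significant)
    }
  }
  rbind(main, do.call(rbind, uni))
}

WITHIN_CASE_VARS <- c("ados", "medication", "iq", "age", "sex", "handedness")

#' Within-case models of significant asymmetries
#'
#' For HDs that were significant in the main analysis, tests association
#' with a clinical/demographic variable among cases only:
#' `HD ~ variable + age + sex + (1 | dataset)` (the variable's own term is
#' dropped from the covariates when it is age or sex), with within-dataset
#' permutation of the variable for the empirical p. Descriptive tier: no
#' multiple-testing correction. Variables non-missing for fewer than
#' `min_n` cases are skipped (returned flagged, not an error).
#'
#' @param cohort A [hemisnet_cohort()].
#' @param targets Data frame with columns `metric` and `node` (NA node =
#'   hemisphere-level) naming the HDs to test, e.g. the significant rows of
#'   [run_node_level_analysis()].
#' @param variable One of `"ados"`, `"medication"`, `"iq"`, `"age"`,
#'   `"sex"`, `"handedness"`.
#' @param config A [hemisnet_config()].
#' @param metrics Optional precomputed [compute_metric_panel()] result.
#' @param min_n Minimum number of cases with the variable non-missing.
#'   Default 20.
#' @return Data frame like [run_node_level_analysis()] with tier
#'   `"within_case"`, plus columns `variable` and `skipped`.
#' @export
run_within_case_models <- function(cohort, targets, variable,
                                   config = hemisnet_config(),
                                   metrics = NULL, min_n = 20L) {
  stopifnot(inherits(cohort, "hemisnet_cohort"))
  variable <- match.arg(variable, WITHIN_CASE_VARS)
  targets <- as.data.frame(targets)
  if (nrow(targets) == 0)
    return(empty_within_case())
  if (is.null(metrics)) {
    networks <- build_networks(cohort, config)
    metrics <- compute_metric_panel(
      networks, config,
      hemisphere = any(is.na(targets$node) |
                         targets$metric %in% HEMI_METRICS))
  }
  cases <- cohort$subjects$diagnosis == "case"
  subj <- cohort$subjects[cases, , drop = FALSE]
  pred <- switch(variable,
    ados = subj$ados_total,
    medication = as.numeric(subj$medication),
    iq = subj$iq,
    age = subj$age,
    sex = as.numeric(subj$sex == "M"),
    handedness = as.numeric(subj$handedness == "L"))
  covars <- setdiff(c("age", "sex"), variable)
  out <- list()
  for (i in seq_len(nrow(targets))) {
    met <- targets$metric[i]
    nod <- targets$node[i]
    hd_all <- if (is.na(nod) || met %in% HEMI_METRICS)
      compute_hd(metrics$hemi[, met, "L"], metrics$hemi[, met, "R"])
    else
      compute_hd(metrics$node[, nod, met, "L"],
                 metrics$node[, nod, met, "R"])
    y <- hd_all[cases]
    usable <- sum(is.finite(pred) & is.finite(y))
    if (usable < min_n || length(unique(pred[is.finite(pred)])) < 2) {
      message("within-case '", variable, "' for ", met,
              ifelse(is.na(nod), "", paste0("/", nod)),
              ": skipped (", usable, " usable cases)")
      row <- data.frame(tier = "within_case", metric = met, node = nod,
                        n_cases = usable, n_controls = 0L,
                        coefficient = NA_real_, t = NA_real_,
                        df = NA_integer_, cohens_d = NA_real_,
                        p_empirical = NA_real_, p_adjusted = NA_real_,
                        significant = NA, variable = variable,
                        skipped = TRUE, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- row
      next
    }
    res <- lmm_permutation_test(
      matrix(y, ncol = 1), subj, "main",
      config$n_permutations, config$rng_seed, NULL,
      predictor = pred,
      global_permutation = config$global_permutation,
      covariates = covars)
    adj <- adjust_pvalues(res$p, "within_case")
    row <- result_row("within_case", met, nod, res, 1L,
                      NA_real_, adj$p_adjusted, adj$significant)
    # effect size only meaningful for binary predictors
    if (variable %in% c("medication", "sex", "handedness")) {
      n1 <- sum(pred == 1, na.rm = TRUE)
      n0 <- sum(pred == 0, na.rm = TRUE)
      row$cohens_d <- cohens_d_from_t(res$t_obs, n1, n0, res$df)
    }
    row$variable <- variable
    row$skipped <- FALSE
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

empty_within_case <- function() {
  data.frame(tier = character(), metric = character(), node = character(),
             n_cases = integer(), n_controls = integer(),
             coefficient = numeric(), t = numeric(), df = integer(),
             cohens_d = numeric(), p_empirical = numeric(),
             p_adjusted = numeric(), significant = logical(),
             variable = character(), skipped = logical(),
             stringsAsFactors = FALSE)
}
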