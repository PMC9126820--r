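#' Trapezoidal area under a metric-vs-sparsity curve
#'
#' @param x Strictly increasing thresholds.
#' @param y Metric values at `x` (vector, or matrix with curves in rows).
#' @return Scalar AUC (or vector, one per row of `y`), in metric units
#'   times sparsity.
#' @export
#' @examples
#' auc_trapezoid(c(0.25, 0.5), c(2, 4))  # 0.75
auc_trapezoid <- function(x, y) {
  if (is.unsorted(x, strictly = TRUE)) stop("thresholds must be increasing")
  if (is.matrix(y)) {
    stopifnot(ncol(y) == length(x))
    w <- diff(x)
    as.numeric((y[, -ncol(y), drop = FALSE] +
                  y[, -1, drop = FALSE]) %*% w) / 2
  } else {
    stopifnot(length(y) == length(x))
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
}

#' Sparsity-sweep sensitivity analysis
#'
#' Re-thresholds the cached weighted networks at every sparsity in
#' `config$sparsity_range` (0.25-0.50 step 0.01 by default), recomputes the
#' node-level metrics at each threshold, integrates each
#' subject/hemisphere/metric curve by the trapezoidal rule, and runs the
#' main mixed-model + permutation analysis on the HDs of the AUCs (HD and
#' AUC commute since both are linear, so HD-of-AUC equals AUC-of-HD).
#' Edge sets are nested across the sweep: the network at a higher sparsity
#' contains every edge retained at a lower one.
#'
#' @inheritParams run_node_level_analysis
#' @param hemisphere Also sweep the hemisphere-level small-world metrics
#'   (runs `n_null` rewired nulls per subject, hemisphere and threshold;
#'   expensive). Default FALSE.
#' @return Object of class `hemisnet_sweep`: list with `thresholds`,
#'   `values` (array n x 34 x metrics x 2 x n_thresholds), `auc` (array
#'   n x 34 x metrics x 2), optional `hemi_values`/`hemi_auc`, and
#'   `results` (the AUC-HD test table, tiers as in the main analysis).
#' @export
run_sparsity_sweep <- function(cohort, config = hemisnet_config(),
                               node_metrics = NODE_METRICS,
                               hemisphere = FALSE, networks = NULL) {
  stopifnot(inherits(cohort, "hemisnet_cohort"))
  if (is.null(networks)) networks <- build_networks(cohort, config)
  node_metrics <- match.arg(node_metrics, NODE_METRICS, several.ok = TRUE)
  sv <- config$sparsity_range
  subj <- dimnames(networks$weighted)[[1]]
  n <- length(subj)
  values <- array(NA_real_,
                  c(n, N_REGIONS, length(node_metrics), 2L, length(sv)),
                  dimnames = list(subj, dk_regions(), node_metrics,
                                  c("L", "R"), sprintf("%.2f", sv)))
  hemi_values <- if (hemisphere)
    array(NA_real_, c(n, 3L, 2L, length(sv)),
          dimnames = list(subj, HEMI_METRICS, c("L", "R"),
                          sprintf("%.2f", sv))) else NULL
  seed_base <- config$rng_seed %% 1000000L
  any_disconnected <- FALSE
  for (s in seq_along(sv)) for (h in 1:2) for (k in seq_len(n)) {
    A <- binarize_by_sparsity(networks$weighted[k, , , h], sv[s])
    nm <- compute_node_metrics(A, metrics = node_metrics)
    for (m in node_metrics) values[k, , m, h, s] <- nm[[m]]
    if (hemisphere) {
      sw <- compute_small_world(A, n_null = config$n_null_networks,
                                rng_seed = seed_base + k + 7L * s,
                                rewire_factor = config$rewire_factor)
      hemi_values[k, , h, s] <- c(sw$gamma, sw$lambda, sw$sigma)
      any_disconnected <- any_disconnected || sw$disconnected
    }
  }
  auc <- array(NA_real_, dim(values)[1:4], dimnames = dimnames(values)[1:4])
  for (m in node_metrics) for (h in 1:2)
    auc[, , m, h] <- matrix(
      auc_trapezoid(sv, matrix(aperm(values[, , m, h, , drop = FALSE],
                                     c(1, 2, 5, 3, 4)),
                               nrow = n * N_REGIONS)),
      nrow = n)
  hemi_auc <- NULL
  if (hemisphere) {
    hemi_auc <- array(NA_real_, dim(hemi_values)[1:3],
                      dimnames = dimnames(hemi_values)[1:3])
    for (h in 1:2)
      hemi_auc[, , h] <- matrix(
        auc_trapezoid(sv, matrix(aperm(hemi_values[, , h, , drop = FALSE],
                                       c(1, 2, 4, 3)), nrow = n * 3L)),
        nrow = n)
  }

  out <- list()
  if (hemisphere) {
    Y <- compute_hd(hemi_auc[, , "L"], hemi_auc[, , "R"])
    res <- lmm_permutation_test(Y, cohort$subjects, "main",
                                config$n_permutations, config$rng_seed,
                                NULL,
                                global_permutation = config$global_permutation)
    d <- cohens_d_from_t(res$t_obs, res$n_cases, res$n_controls, res$df)
    adj <- adjust_pvalues(res$p, "hemisphere",
                          alpha = config$alpha_hemisphere)
    for (j in 1:3)
      out[[length(out) + 1L]] <- result_row(
        "hemisphere", HEMI_METRICS[j], NA_character_, res, j, d[j],
        adj$p_adjusted[j], adj$significant[j])
  }
  for (m in node_metrics) {
    Y <- compute_hd(auc[, , m, "L"], auc[, , m, "R"])
    res <- lmm_permutation_test(Y, cohort$subjects, "main",
                                config$n_permutations, config$rng_seed,
                                NULL,
                                global_permutation = config$global_permutation)
    d <- cohens_d_from_t(res$t_obs, res$n_cases, res$n_controls, res$df)
    adj <- adjust_pvalues(res$p, "node", alpha = config$alpha_node)
    for (j in seq_len(N_REGIONS))
      out[[length(out) + 1L]] <- result_row(
        "node", m, dk_regions()[j], res, j, d[j],
        adj$p_adjusted[j], adj$significant[j])
  }
  structure(list(thresholds = sv, values = values, auc = auc,
                 hemi_values = hemi_values, hemi_auc = hemi_auc,
                 results = do.call(rbind, out),
                 disconnected_seen = any_disconnected),
            class = "hemisnet_sweep")
}

#' Long-format export of sweep curves
#'
#' @param sweep A [run_sparsity_sweep()] result.
#' @return Data frame with columns subject, hemisphere, metric, node,
#'   sparsity, value.
#' @export
sweep_to_table <- function(sweep) {
  stopifnot(inherits(sweep, "hemisnet_sweep"))
  dn <- dimnames(sweep$values)
  out <- expand.grid(subject = dn[[1]], node = dn[[2]], metric = dn[[3]],
                     hemisphere = dn[[4]], sparsity = sweep$thresholds,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$value <- as.vector(sweep$values)
  out[, c("subject", "hemisphere", "metric", "node", "sparsity", "value")]
}

#' Model-variant sensitivity analysis
#'
#' Re-runs the case-control analysis with (i) a centred quadratic age term
#' and (ii) the subject's mean cortical thickness as an extra fixed effect,
#' to check that the main-analysis effects are not driven by non-linear age
#' dependence or global thickness differences.
#'
#' @inheritParams run_node_level_analysis
#' @return Data frame of test results with an extra `variant` column
#'   (`"nonlinear_age"` / `"global_thickness"`).
#' @export
run_model_variants <- function(cohort, config = hemisnet_config(),
                               node_metrics = NODE_METRICS,
                               hemisphere = TRUE,
                               networks = NULL, metrics = NULL) {
  if (is.null(networks)) networks <- build_networks(cohort, config)
  if (is.null(metrics))
    metrics <- compute_metric_panel(networks, config,
                                    node_metrics = node_metrics,
                                    hemisphere = hemisphere)
  out <- list()
  for (v in c("nonlinear_age", "global_thickness")) {
    r <- run_node_level_analysis(cohort, config, node_metrics, hemisphere,
                                 networks, metrics, variant = v)
    r$variant <- v
    out[[v]] <- r
  }
  do.call(rbind, out)
}
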