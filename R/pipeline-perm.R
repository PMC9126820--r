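# Full-pipeline permutation scheme.
#
# The default permutation test swaps diagnosis labels and refits the mixed
# model on the *fixed* metric outcomes. That is exact only if the metric
# outcomes are exchangeable between cases and controls under the null —
# which fails in small samples, because controls define the standardization
# reference: their z-scores are constrained (they average to 0 per
# dataset/region) while cases' are not, so case and control metric
# distributions differ slightly even without any group effect. The bias is
# O(1/n_controls): negligible for consortium-sized datasets, material when
# datasets contribute only a handful of controls.
#
# The pipeline scheme removes the problem by re-running the entire
# construction under each relabeling — pseudo-controls define the
# reference, all subjects are re-standardized, networks are rebuilt and
# re-thresholded, metrics recomputed, and the model refit — which is exact
# at any control count because the raw thickness data are exchangeable.
# Degree centrality has a compiled fast path; the other node metrics go
# through the R construction and are correspondingly slower.

pipeline_perm_core <- function(cohort, config, metric, n_perm, rng_seed,
                               nodes = dk_regions()) {
  sub <- cohort$subjects
  des <- build_design(sub, "main")
  if (any(!des$keep))
    stop("pipeline permutation requires complete age/sex for all subjects")
  X <- des$X
  grp <- factor(sub$dataset_id)
  diag01 <- X[, des$pcol]
  set.seed(as.integer(rng_seed))
  P <- cbind(diag01,
             make_permutations(diag01, grp, n_perm,
                               global = config$global_permutation))
  m_keep <- retained_edges(config$sparsity)
  thickL <- cohort$thickness[, region_columns("L"), drop = FALSE]
  thickR <- cohort$thickness[, region_columns("R"), drop = FALSE]
  g0 <- as.integer(grp) - 1L
  node_idx <- match(nodes, dk_regions())
  if (anyNA(node_idx)) stop("unknown node(s): ",
                            paste(nodes[is.na(node_idx)], collapse = ", "))

  if (identical(metric, "degree")) {
    cpp <- pipeline_degree_perm_cpp(thickL, thickR, g0, nlevels(grp), P,
                                    m_keep, X, des$pcol - 1L,
                                    node_idx - 1L)
    tmat <- cpp$t
    Y0 <- cpp$y_obs[, node_idx, drop = FALSE]
  } else {
    tmat <- matrix(NA_real_, ncol(P), N_REGIONS)
    for (b in seq_len(ncol(P))) {
      coh_b <- cohort
      coh_b$subjects$diagnosis <- ifelse(P[, b] == 1, "case", "control")
      z <- standardize(coh_b, compute_control_reference(
        coh_b, pooled = config$pooled_reference))
      Y <- matrix(NA_real_, nrow(z), N_REGIONS)
      for (k in seq_len(nrow(z))) {
        vl <- compute_node_metrics(binarize_by_sparsity(
          build_weighted_network(z[k, region_columns("L")]),
          config$sparsity), metrics = metric)[[metric]]
        vr <- compute_node_metrics(binarize_by_sparsity(
          build_weighted_network(z[k, region_columns("R")]),
          config$sparsity), metrics = metric)[[metric]]
        Y[k, ] <- vl - vr
      }
      if (b == 1L) Y0 <- Y[, node_idx, drop = FALSE]
      tmat[b, ] <- reml_perm_t_cpp(X, Y, g0, nlevels(grp),
                                   des$pcol - 1L, P[, b, drop = FALSE])
    }
    tmat <- tmat[, node_idx, drop = FALSE]
  }
  t_obs <- tmat[1, ]
  t_perm <- tmat[-1, , drop = FALSE]
  fail <- colSums(!is.finite(t_perm))
  if (any(fail > 0.01 * n_perm))
    stop("pipeline permutation: mixed-model fit failed in more than 1% ",
         "of permutations")
  p <- vapply(seq_along(node_idx), function(j) {
    tp <- t_perm[, j]
    ok <- is.finite(tp)
    (1 + sum(abs(tp[ok]) >= abs(t_obs[j]))) / (1 + sum(ok))
  }, numeric(1))
  # observed coefficients from the observed (unpermuted) construction
  coefs <- numeric(length(node_idx))
  for (j in seq_along(node_idx)) {
    f <- reml_fit_cpp(X, Y0[, j], g0, nlevels(grp))
    coefs[j] <- f$beta[des$pcol]
  }
  list(t_obs = t_obs, p = p, coefficient = coefs, nodes = nodes,
       df = nrow(X) - ncol(X), n = nrow(X),
       n_cases = sum(diag01 == 1), n_controls = sum(diag01 == 0),
       n_excluded = 0L)
}

#' Exact full-pipeline permutation test of node-metric asymmetry
#'
#' Case-control test of the hemispheric difference of one node-level
#' metric in which every permutation re-runs the whole construction —
#' control reference, standardization, networks, thresholding, metric —
#' under the permuted labels before refitting the mixed model. This keeps
#' the test exact when controls define the standardization reference,
#' whereas the default (model-stage) label swap is slightly
#' anticonservative when datasets contribute few controls (the reference
#' constrains the controls' z-scores). Prefer this scheme for cohorts with
#' small per-dataset control counts; at consortium scale the two agree.
#' Degree centrality uses a compiled fast path; other metrics re-run the R
#' construction per permutation and are markedly slower.
#'
#' @param cohort A [hemisnet_cohort()].
#' @param config A [hemisnet_config()]; `sparsity`, `n_permutations`,
#'   `rng_seed` and `global_permutation` are honoured.
#' @param metric One node metric (`"degree"`, `"clustering"`, `"eglob"`,
#'   `"eloc"`).
#' @param nodes Regions whose HD is tested (degrees are always computed on
#'   the full 34-node networks); the BH correction spans the tested set.
#'   Default: all 34 regions.
#' @return Data frame with tier `"node"`, one row per tested region:
#'   coefficient, t, df, Cohen's d, empirical p, BH-adjusted p,
#'   significance at the node-tier threshold.
#' @export
run_pipeline_permutation <- function(cohort, config = hemisnet_config(),
                                     metric = "degree",
                                     nodes = dk_regions()) {
  stopifnot(inherits(cohort, "hemisnet_cohort"))
  metric <- match.arg(metric, NODE_METRICS)
  res <- pipeline_perm_core(cohort, config, metric,
                            config$n_permutations, config$rng_seed, nodes)
  d <- cohens_d_from_t(res$t_obs, res$n_cases, res$n_controls, res$df)
  adj <- adjust_pvalues(res$p, "node", alpha = config$alpha_node)
  out <- lapply(seq_along(res$nodes), function(j)
    result_row("node", metric, res$nodes[j], res, j, d[j],
               adj$p_adjusted[j], adj$significant[j]))
  do.call(rbind, out)
}
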