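#' Fit the full hemispheric network asymmetry analysis
#'
#' One call from a cohort to the complete case-control inference: builds
#' each subject's left and right intra-hemispheric covariance networks,
#' computes the topological metric panel, tests every hemispheric
#' difference with the random-intercept mixed model and label-swap
#' permutations, applies the tiered multiple-testing correction, runs
#' unilateral follow-ups for significant HDs, and (when any
#' degree-centrality HD is significant) the descriptive edge-level
#' analysis around those seed regions.
#'
#' @param cohort A [hemisnet_cohort()] (from [read_cohort()] or
#'   [generate_cohort()]).
#' @param config A [hemisnet_config()].
#' @param node_metrics Node-level metrics to analyse.
#' @param hemisphere Include the hemisphere-level gamma/lambda/sigma tier.
#' @param edge_seeds `NULL` to auto-select seeds (regions with significant
#'   degree-centrality HD), a character vector to force seeds, or `FALSE`
#'   to skip the edge tier.
#' @return Object of class `hemisnet`: list with `results` (main +
#'   unilateral test table), `edge_results`, `metrics`, `networks`,
#'   `cohort`, `config` and a reproducibility `manifest`.
#' @seealso [run_node_level_analysis()], [run_edge_level_analysis()],
#'   [run_sparsity_sweep()], [run_model_variants()]
#' @export
#' @examples
#' \donttest{
#' coh <- make_fixture("tiny")
#' cfg <- hemisnet_config(n_permutations = 99, n_null_networks = 5)
#' fit <- hemisnet(coh, cfg)
#' print(fit)
#' head(coef(fit))
#' }
hemisnet <- function(cohort, config = hemisnet_config(),
                     node_metrics = NODE_METRICS, hemisphere = TRUE,
                     edge_seeds = NULL) {
  stopifnot(inherits(cohort, "hemisnet_cohort"))
  t0 <- proc.time()[["elapsed"]]
  networks <- build_networks(cohort, config)
  metrics <- compute_metric_panel(networks, config,
                                  node_metrics = node_metrics,
                                  hemisphere = hemisphere)
  results <- run_node_level_analysis(cohort, config, node_metrics,
                                     hemisphere, networks, metrics)
  if (isFALSE(edge_seeds)) {
    seeds <- character(0)
  } else if (is.null(edge_seeds)) {
    seeds <- select_seeds(results)
  } else {
    seeds <- edge_seeds
  }
  edge_results <- run_edge_level_analysis(cohort, networks, seeds, config)
  manifest <- list(
    n_subjects = nrow(cohort$subjects),
    n_cases = sum(cohort$subjects$diagnosis == "case"),
    n_controls = sum(cohort$subjects$diagnosis == "control"),
    n_datasets = length(unique(cohort$subjects$dataset_id)),
    sparsity = config$sparsity,
    n_permutations = config$n_permutations,
    n_null_networks = config$n_null_networks,
    rng_seed = config$rng_seed,
    edge_seeds = seeds,
    n_disconnected_networks = sum(metrics$disconnected),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2)
  )
  structure(list(results = results, edge_results = edge_results,
                 metrics = metrics, networks = networks, cohort = cohort,
                 config = config, manifest = manifest),
            class = "hemisnet")
}

#' @export
print.hemisnet <- function(x, ...) {
  m <- x$manifest
  cat("hemisnet asymmetry analysis\n")
  cat(sprintf("  %d subjects (%d cases / %d controls), %d datasets, S = %.2f\n",
              m$n_subjects, m$n_cases, m$n_controls, m$n_datasets,
              m$sparsity))
  main <- x$results[x$results$tier %in% c("hemisphere", "node"), ]
  cat(sprintf("  %d HD tests (%d hemisphere-level, %d node-level), %d permutations each\n",
              nrow(main), sum(main$tier == "hemisphere"),
              sum(main$tier == "node"), m$n_permutations))
  sig <- main[main$significant, ]
  if (nrow(sig) == 0) {
    cat("  no significant case-control asymmetry differences\n")
  } else {
    cat("  significant:", paste(
      ifelse(is.na(sig$node), sig$metric,
             paste0(sig$metric, "[", sig$node, "]")), collapse = ", "),
      "\n")
  }
  if (length(m$edge_seeds))
    cat("  edge-level seeds:", paste(m$edge_seeds, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hemisnet <- function(object, ...) {
  main <- object$results[object$results$tier %in%
                           c("hemisphere", "node"), ]
  structure(list(manifest = object$manifest, main = main,
                 significant = main[main$significant, ],
                 edge = object$edge_results,
                 unilateral = object$results[grepl("^unilateral",
                                                   object$results$tier), ]),
            class = "summary.hemisnet")
}

#' @export
print.summary.hemisnet <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "Case-control network asymmetry analysis: %d subjects, %d datasets\n",
    m$n_subjects, m$n_datasets))
  cat(sprintf("Sparsity %.2f, %d permutations, seed %d\n\n", m$sparsity,
              m$n_permutations, m$rng_seed))
  cat("Significant hemispheric-difference effects:\n")
  if (nrow(x$significant) == 0) {
    cat("  (none)\n")
  } else {
    df <- x$significant
    df$label <- ifelse(is.na(df$node), df$metric,
                       paste0(df$metric, "[", df$node, "]"))
    print(df[, c("label", "coefficient", "t", "cohens_d", "p_empirical",
                 "p_adjusted")], row.names = FALSE, digits = 4)
  }
  if (nrow(x$edge)) {
    cat(sprintf("\nEdge tier: %d edge HDs tested, %d significant\n",
                nrow(x$edge), sum(x$edge$significant)))
  }
  invisible(x)
}

#' @export
coef.hemisnet <- function(object, tier = c("node", "hemisphere"), ...) {
  tier <- match.arg(tier)
  r <- object$results[object$results$tier == tier, ]
  nm <- if (tier == "node") paste0(r$metric, "[", r$node, "]") else r$metric
  stats::setNames(r$coefficient, nm)
}

#' Effect-size plot of node-level asymmetry results
#'
#' Cohen's d of the diagnosis effect on each region's HD for one node
#' metric, with significant regions highlighted.
#'
#' @param x A [hemisnet()] fit.
#' @param metric Node metric to plot. Default `"degree"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted subset of the results table.
#' @export
plot.hemisnet <- function(x, metric = "degree", ...) {
  r <- x$results[x$results$tier == "node" & x$results$metric == metric, ]
  if (nrow(r) == 0) stop("no node-tier results for metric '", metric, "'")
  op <- par(mar = c(4, 9, 2, 1))
  on.exit(par(op))
  ord <- order(r$cohens_d)
  plot(r$cohens_d[ord], seq_len(nrow(r)), yaxt = "n",
       xlab = "Cohen's d (case-control, HD)", ylab = "",
       main = paste0(metric, " asymmetry"),
       pch = ifelse(r$significant[ord], 19, 1),
       col = ifelse(r$significant[ord], "firebrick", "grey40"), ...)
  axis(2, at = seq_len(nrow(r)), labels = r$node[ord], las = 2,
       cex.axis = 0.6)
  abline(v = 0, lty = 2, col = "grey60")
  invisible(r)
}

#' Write a JSON run manifest
#'
#' Records configuration, seed and cohort counts for reproducibility.
#'
#' @param fit A [hemisnet()] fit.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(fit, path) {
  stopifnot(inherits(fit, "hemisnet"))
  jsonlite::write_json(
    list(manifest = fit$manifest, config = unclass(fit$config)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
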