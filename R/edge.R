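#' Seed-edge hemispheric differences for one subject
#'
#' For a seed region, the HD of each of its 33 unthresholded edges:
#' `hd_j = w_L(seed, j) - w_R(seed, j)`. Edge weights come from the
#' weighted (not binarized) networks, so these values are independent of
#' the sparsity setting.
#'
#' @param weighted_left,weighted_right 34 x 34 weighted matrices for one
#'   subject (region-named).
#' @param seed Seed region base name.
#' @return Data frame with columns `partner` (33 regions) and `hd`.
#' @export
extract_seed_edge_hd <- function(weighted_left, weighted_right, seed) {
  regions <- dk_regions()
  j <- match(seed, regions)
  if (is.na(j)) stop("unknown seed region: ", seed)
  partners <- regions[-j]
  data.frame(partner = partners,
             hd = compute_hd(weighted_left[j, -j], weighted_right[j, -j]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Descriptive edge-level case-control analysis
#'
#' For each seed region (by default every region whose degree-centrality
#' HD passed the node tier), fits the same random-intercept mixed model to
#' each of the 33 seed-partner edge HDs, with permutation p-values and BH
#' FDR across the 33 edges of that seed.
#'
#' @param cohort A [hemisnet_cohort()].
#' @param networks A [build_networks()] result (weighted matrices are
#'   used).
#' @param seeds Character vector of seed regions; an empty vector returns
#'   an empty result. Use [run_node_level_analysis()] output to auto-select
#'   via [select_seeds()].
#' @param config A [hemisnet_config()].
#' @return Data frame of test results with tier `"edge"`, `metric` =
#'   `"edge_<seed>"` and `node` = partner region (33 rows per seed).
#' @export
run_edge_level_analysis <- function(cohort, networks, seeds,
                                    config = hemisnet_config()) {
  stopifnot(inherits(cohort, "hemisnet_cohort"),
            inherits(networks, "hemisnet_networks"))
  regions <- dk_regions()
  bad <- setdiff(seeds, regions)
  if (length(bad)) stop("unknown seed region(s): ",
                        paste(bad, collapse = ", "))
  out <- list()
  for (seed in seeds) {
    j <- match(seed, regions)
    Y <- compute_hd(networks$weighted[, j, -j, "L"],
                    networks$weighted[, j, -j, "R"])
    res <- lmm_permutation_test(Y, cohort$subjects, "main",
                                config$n_permutations, config$rng_seed,
                                NULL,
                                global_permutation = config$global_permutation)
    d <- cohens_d_from_t(res$t_obs, res$n_cases, res$n_controls, res$df)
    adj <- adjust_pvalues(res$p, "edge", alpha = config$alpha_edge)
    for (k in seq_len(ncol(Y)))
      out[[length(out) + 1L]] <- result_row(
        "edge", paste0("edge_", seed), regions[-j][k], res, k, d[k],
        adj$p_adjusted[k], adj$significant[k])
  }
  if (!length(out))
    return(data.frame(tier = character(), metric = character(),
                      node = character(), n_cases = integer(),
                      n_controls = integer(), coefficient = numeric(),
                      t = numeric(), df = integer(), cohens_d = numeric(),
                      p_empirical = numeric(), p_adjusted = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Auto-select edge-analysis seeds from main-analysis results
#'
#' Regions whose degree-centrality HD was significant at the node tier.
#'
#' @param results Output of [run_node_level_analysis()].
#' @return Character vector of region names (possibly empty).
#' @export
select_seeds <- function(results) {
  results <- as.data.frame(results)
  sel <- results$tier == "node" & results$metric == "degree" &
    results$significant
  unique(results$node[sel & !is.na(sel)])
}
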