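#' Analysis configuration
#'
#' Bundles every tunable of the asymmetry pipeline. Defaults follow the main
#' analysis: sparsity 0.4, 10,000 label-swap permutations, 100 degree-matched
#' null networks for the small-world normalization, Bonferroni 0.05/3 at the
#' hemisphere tier and FDR 0.05/4 at the node tier.
#'
#' @param sparsity Fraction of strongest edges retained when binarizing,
#'   in (0, 1]. Default 0.4 (224 of 561 edges).
#' @param sparsity_range Ordered thresholds for the sensitivity sweep.
#'   Default `seq(0.25, 0.50, by = 0.01)` (26 values).
#' @param n_permutations Label-swap permutations per test. Default 10000.
#' @param n_null_networks Rewired null networks per subject/hemisphere used
#'   for the gamma/lambda normalization. Default 100.
#' @param rewire_factor Attempted degree-preserving edge swaps per null,
#'   as a multiple of the edge count. Default 10.
#' @param rng_seed Integer seed controlling permutations and null networks.
#' @param alpha_hemisphere Per-family alpha for the 3 hemisphere-level tests
#'   (Bonferroni). Default 0.05.
#' @param alpha_node Threshold applied to BH-adjusted node-level p-values,
#'   0.05/4 by default (four node-level metrics tested).
#' @param alpha_edge FDR level for the 33 edges of one seed. Default 0.05.
#' @param nonlinear_age Add a centred quadratic age term to the fixed
#'   effects. Default FALSE.
#' @param global_thickness_covariate Add each subject's mean cortical
#'   thickness over all 68 regions as a fixed effect. Default FALSE.
#' @param pooled_reference Standardize against controls pooled over datasets
#'   instead of within-dataset (the default, matching per-scanner
#'   referencing).
#' @param global_permutation Swap diagnosis labels across the whole cohort
#'   instead of within dataset. Default FALSE (within-dataset swapping
#'   preserves each dataset's case/control count).
#' @param comma Read/write comma-separated rather than tab-separated tables.
#'
#' @return An object of class `hemisnet_config` (a validated list).
#' @export
#' @examples
#' cfg <- hemisnet_config(sparsity = 0.4, n_permutations = 1000)
#' cfg$sparsity
hemisnet_config <- function(sparsity = 0.4,
                            sparsity_range = seq(0.25, 0.50, by = 0.01),
                            n_permutations = 10000L,
                            n_null_networks = 100L,
                            rewire_factor = 10L,
                            rng_seed = 1L,
                            alpha_hemisphere = 0.05,
                            alpha_node = 0.05 / 4,
                            alpha_edge = 0.05,
                            nonlinear_age = FALSE,
                            global_thickness_covariate = FALSE,
                            pooled_reference = FALSE,
                            global_permutation = FALSE,
                            comma = FALSE) {
  cfg <- list(
    sparsity = as.numeric(sparsity),
    sparsity_range = as.numeric(sparsity_range),
    n_permutations = as.integer(n_permutations),
    n_null_networks = as.integer(n_null_networks),
    rewire_factor = as.integer(rewire_factor),
    rng_seed = as.integer(rng_seed),
    alpha_hemisphere = as.numeric(alpha_hemisphere),
    alpha_node = as.numeric(alpha_node),
    alpha_edge = as.numeric(alpha_edge),
    nonlinear_age = isTRUE(nonlinear_age),
    global_thickness_covariate = isTRUE(global_thickness_covariate),
    pooled_reference = isTRUE(pooled_reference),
    global_permutation = isTRUE(global_permutation),
    comma = isTRUE(comma)
  )
  validate_config(cfg)
  structure(cfg, class = "hemisnet_config")
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$sparsity) == 1)
  if (!is.finite(cfg$sparsity) || cfg$sparsity <= 0 || cfg$sparsity > 1)
    stop("`sparsity` must lie in (0, 1], got ", cfg$sparsity)
  if (any(!is.finite(cfg$sparsity_range)) ||
      any(cfg$sparsity_range <= 0) || any(cfg$sparsity_range > 1))
    stop("all values in `sparsity_range` must lie in (0, 1]")
  if (is.unsorted(cfg$sparsity_range, strictly = TRUE))
    stop("`sparsity_range` must be strictly increasing")
  if (is.na(cfg$n_permutations) || cfg$n_permutations < 1L)
    stop("`n_permutations` must be >= 1")
  if (is.na(cfg$n_null_networks) || cfg$n_null_networks < 1L)
    stop("`n_null_networks` must be >= 1")
  for (a in c("alpha_hemisphere", "alpha_node", "alpha_edge"))
    if (!is.finite(cfg[[a]]) || cfg[[a]] <= 0 || cfg[[a]] >= 1)
      stop("`", a, "` must lie in (0, 1)")
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' The YAML file mirrors [hemisnet_config()] field for field; unknown keys
#' are rejected so typos do not silently fall back to defaults.
#'
#' @param path File path.
#' @param cfg A `hemisnet_config` object.
#' @return `read_config()` returns a `hemisnet_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(hemisnet_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(hemisnet_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "hemisnet_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.hemisnet_config <- function(x, ...) {
  cat("hemisnet analysis configuration\n")
  cat(sprintf("  sparsity: %.2f (%d of %d edges retained)\n",
              x$sparsity, retained_edges(x$sparsity), N_PAIRS))
  cat(sprintf("  sweep: %.2f-%.2f in %d steps\n", min(x$sparsity_range),
              max(x$sparsity_range), length(x$sparsity_range)))
  cat(sprintf("  permutations: %d | null networks: %d | seed: %d\n",
              x$n_permutations, x$n_null_networks, x$rng_seed))
  cat(sprintf("  alpha: hemisphere %.4g (Bonferroni), node FDR %.4g, edge FDR %.4g\n",
              x$alpha_hemisphere, x$alpha_node, x$alpha_edge))
  flags <- c("nonlinear_age", "global_thickness_covariate",
             "pooled_reference", "global_permutation")[c(
               x$nonlinear_age, x$global_thickness_covariate,
               x$pooled_reference, x$global_permutation)]
  if (length(flags)) cat("  variants:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}
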