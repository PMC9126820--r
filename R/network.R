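#' Per-dataset control reference for standardization
#'
#' Mean and sample SD (denominator n-1) of every regional thickness column,
#' computed from control subjects only, within each dataset (scanners
#' differ between datasets, so networks are constructed within dataset). A
#' pooled reference over all controls is available behind
#' `pooled = TRUE`.
#'
#' @param cohort A [hemisnet_cohort()].
#' @param pooled Pool controls across datasets instead of per dataset.
#' @return Object of class `hemisnet_control_reference`: list with matrices
#'   `mean` and `sd` (datasets x 68 columns; a single `"pooled"` row when
#'   pooled) and the `pooled` flag.
#' @export
compute_control_reference <- function(cohort, pooled = FALSE) {
  stopifnot(inherits(cohort, "hemisnet_cohort"))
  ctrl <- cohort$subjects$diagnosis == "control"
  groups <- if (pooled) rep("pooled", nrow(cohort$subjects)) else
    cohort$subjects$dataset_id
  ids <- sort(unique(groups))
  m <- matrix(NA_real_, length(ids), ncol(cohort$thickness),
              dimnames = list(ids, colnames(cohort$thickness)))
  s <- m
  for (d in ids) {
    sel <- ctrl & groups == d
    if (sum(sel) < 2L)
      stop("dataset '", d, "' has fewer than 2 controls; ",
           "control SD is undefined")
    x <- cohort$thickness[sel, , drop = FALSE]
    m[d, ] <- colMeans(x)
    s[d, ] <- apply(x, 2, stats::sd)
  }
  zero <- which(s == 0, arr.ind = TRUE)
  if (nrow(zero))
    stop(sprintf(
      "control SD is zero for dataset '%s', region '%s'",
      ids[zero[1, 1]], colnames(s)[zero[1, 2]]))
  structure(list(mean = m, sd = s, pooled = pooled),
            class = "hemisnet_control_reference")
}

#' Standardize thickness against the control reference
#'
#' `z = (t - control_mean) / control_sd`, each subject scored against the
#' reference of its own dataset. Control subjects of a dataset therefore
#' have per-region mean 0 and sample SD 1; cases need not.
#'
#' @param cohort A [hemisnet_cohort()].
#' @param ref A [compute_control_reference()] result.
#' @return Numeric matrix of z-scores, same shape as `cohort$thickness`.
#' @export
standardize <- function(cohort, ref) {
  stopifnot(inherits(cohort, "hemisnet_cohort"),
            inherits(ref, "hemisnet_control_reference"))
  groups <- if (ref$pooled) rep("pooled", nrow(cohort$subjects)) else
    cohort$subjects$dataset_id
  missing_ds <- setdiff(unique(groups), rownames(ref$mean))
  if (length(missing_ds))
    stop("no control reference for dataset(s): ",
         paste(missing_ds, collapse = ", "))
  i <- match(groups, rownames(ref$mean))
  (cohort$thickness - ref$mean[i, , drop = FALSE]) /
    ref$sd[i, , drop = FALSE]
}

#' Weighted intra-hemispheric covariance network for one subject
#'
#' Edge similarity between regions i and j is the Gaussian kernel of their
#' standardized thickness difference, `w_ij = exp(-(z_i - z_j)^2 / 2)`, so
#' w is in (0, 1] with w = 1 iff z_i = z_j. Because binarization keeps only
#' the rank order of weights, any strictly decreasing function of
#' |z_i - z_j| yields identical binary networks; the kernel choice only
#' matters for the unthresholded edge-level analysis.
#'
#' @param z Numeric vector of 34 finite z-scores (one hemisphere).
#' @return Symmetric 34 x 34 weight matrix, zero diagonal, dimnames from
#'   `names(z)` if present.
#' @export
#' @examples
#' z <- rnorm(34); w <- build_weighted_network(z)
#' w[1, 2] == exp(-(z[1] - z[2])^2 / 2)
build_weighted_network <- function(z) {
  if (any(!is.finite(z)))
    stop("non-finite z-score in input")
  d <- outer(z, z, "-")
  w <- exp(-d^2 / 2)
  diag(w) <- 0
  if (!is.null(names(z))) dimnames(w) <- list(names(z), names(z))
  w
}

# edges retained at sparsity S on an n-node network
retained_edges <- function(sparsity, n_nodes = N_REGIONS) {
  as.integer(floor(sparsity * choose(n_nodes, 2)))
}

#' Binarize a weighted network at a sparsity threshold
#'
#' Keeps exactly `floor(S * n_pairs)` strongest edges (224 of 561 at
#' S = 0.4 on 34 nodes) and sets them to 1, the rest to 0, so every
#' subject's network has the identical edge count. Ties are broken
#' deterministically by upper-triangle (column-major) pair index after
#' sorting on weight descending; ties have measure zero for continuous
#' data.
#'
#' @param w Symmetric weight matrix with zero diagonal.
#' @param sparsity Fraction of edges retained, in (0, 1].
#' @return Binary symmetric matrix of the same dimension.
#' @export
binarize_by_sparsity <- function(w, sparsity) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop("`w` must be a square matrix")
  if (length(sparsity) != 1 || !is.finite(sparsity) ||
      sparsity <= 0 || sparsity > 1)
    stop("`sparsity` must lie in (0, 1]")
  n <- nrow(w)
  ut <- upper.tri(w)
  wt <- w[ut]
  m <- retained_edges(sparsity, n)
  keep <- order(-wt, seq_along(wt))[seq_len(m)]
  bv <- numeric(length(wt))
  bv[keep] <- 1
  b <- matrix(0, n, n, dimnames = dimnames(w))
  b[ut] <- bv
  b + t(b)
}

#' Build all subject networks for a cohort
#'
#' Standardizes the cohort, builds the weighted left- and right-hemisphere
#' networks for every subject, and binarizes them at the configured
#' sparsity. Weighted networks are cached so sensitivity sweeps only
#' re-threshold.
#'
#' @param cohort A [hemisnet_cohort()].
#' @param config A [hemisnet_config()].
#' @return Object of class `hemisnet_networks`: list with `weighted` and
#'   `binary` arrays of dim `c(n_subjects, 34, 34, 2)` (last margin L, R),
#'   the z-score matrix `z`, the control `reference`, and `sparsity`.
#' @export
build_networks <- function(cohort, config = hemisnet_config()) {
  ref <- compute_control_reference(cohort, pooled = config$pooled_reference)
  z <- standardize(cohort, ref)
  n <- nrow(z)
  regions <- dk_regions()
  weighted <- array(NA_real_, c(n, N_REGIONS, N_REGIONS, 2L),
                    dimnames = list(rownames(z), regions, regions,
                                    c("L", "R")))
  binary <- weighted
  for (h in 1:2) {
    cols <- region_columns(c("L", "R")[h])
    for (k in seq_len(n)) {
      w <- build_weighted_network(z[k, cols])
      weighted[k, , , h] <- w
      binary[k, , , h] <- binarize_by_sparsity(w, config$sparsity)
    }
  }
  structure(list(weighted = weighted, binary = binary, z = z,
                 reference = ref, sparsity = config$sparsity),
            class = "hemisnet_networks")
}

#' @export
print.hemisnet_networks <- function(x, ...) {
  cat(sprintf(
    "hemisnet networks: %d subjects x 2 hemispheres, %d nodes, %d of %d edges retained (S = %.2f)\n",
    dim(x$weighted)[1], N_REGIONS, retained_edges(x$sparsity), N_PAIRS,
    x$sparsity))
  invisible(x)
}

#' Export one subject's networks as labeled matrix text files
#'
#' Writes `<subject>_<L|R>_<weighted|binary>.tsv` square matrices with
#' region-labeled rows and columns.
#'
#' @param networks A [build_networks()] result.
#' @param subject_id Subject to export.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths written.
#' @export
export_subject_networks <- function(networks, subject_id, dir = ".") {
  stopifnot(inherits(networks, "hemisnet_networks"))
  k <- match(subject_id, dimnames(networks$weighted)[[1]])
  if (is.na(k)) stop("unknown subject: ", subject_id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (h in c("L", "R")) for (kind in c("weighted", "binary")) {
    p <- file.path(dir, sprintf("%s_%s_%s.tsv", subject_id, h, kind))
    utils::write.table(networks[[kind]][k, , , h], p, sep = "\t",
                       quote = FALSE, col.names = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
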