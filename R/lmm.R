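#' Hemispheric difference
#'
#' `HD = Left - Right`; positive values indicate leftward asymmetry.
#' Non-finite inputs propagate as `NA` (counted and reported downstream
#' rather than erroring).
#'
#' @param left,right Metric values (vectors recycle as usual).
#' @return `left - right`, with non-finite inputs mapped to `NA`.
#' @export
#' @examples
#' compute_hd(10, 7)  # 3, leftward
compute_hd <- function(left, right) {
  out <- left - right
  out[!is.finite(left) | !is.finite(right)] <- NA_real_
  out
}

# Build the fixed-effects design for the case-control models.
# Returns list(X, pcol, groups, keep, n_cases, n_controls).
build_design <- function(subjects, variant = "main",
                         global_thickness = NULL,
                         predictor = NULL) {
  stopifnot(is.data.frame(subjects))
  age <- subjects$age
  sexM <- as.numeric(subjects$sex == "M")
  if (is.null(predictor)) predictor <- as.numeric(subjects$diagnosis == "case")
  keep <- is.finite(age) & is.finite(sexM) & is.finite(predictor)
  if (identical(variant, "global_thickness")) {
    if (is.null(global_thickness))
      stop("variant 'global_thickness' needs the per-subject mean thickness")
    keep <- keep & is.finite(global_thickness)
  }
  X <- cbind(intercept = 1, predictor = predictor, age = age, sex = sexM)
  if (identical(variant, "nonlinear_age")) {
    age_c <- age - mean(age[keep])
    X <- cbind(X, age2 = age_c^2)
  } else if (identical(variant, "global_thickness")) {
    X <- cbind(X, global_thickness = global_thickness)
  } else if (!variant %in% c("main", "unilateral_left", "unilateral_right")) {
    stop("unknown model variant: ", variant)
  }
  list(X = X, pcol = 2L, groups = subjects$dataset_id, keep = keep)
}

check_model_inputs <- function(y, X, groups, diagnosis) {
  n <- length(y)
  if (n <= ncol(X))
    stop("too few subjects (", n, ") for ", ncol(X), " fixed effects")
  if (length(unique(groups)) < 2L)
    stop("need at least 2 datasets for the random-intercept model")
  if (!is.null(diagnosis) && length(unique(diagnosis)) < 2L)
    stop("both diagnosis groups must be present")
  if (stats::sd(y) == 0)
    stop("outcome is constant; model is undefined")
  invisible(TRUE)
}

#' Fit the case-control linear mixed model
#'
#' Random-intercept model `outcome ~ diagnosis + age + sex + (1 | dataset)`,
#' estimated by restricted maximum likelihood (profiled over the
#' between-dataset variance ratio). Variants add a centred quadratic age
#' term (`nonlinear_age`) or the subject's mean cortical thickness
#' (`global_thickness`); the unilateral variants use the same covariates
#' with the raw left or right metric supplied as `outcome`. Subjects with
#' missing age, sex or outcome are excluded with a reported count.
#'
#' @param outcome Per-subject outcome (an HD, or a raw unilateral metric).
#' @param subjects Covariates data frame (see [hemisnet_cohort()]).
#' @param variant One of `"main"`, `"nonlinear_age"`, `"global_thickness"`,
#'   `"unilateral_left"`, `"unilateral_right"`.
#' @param global_thickness Per-subject mean thickness over all 68 regions;
#'   required by the `global_thickness` variant.
#' @return Object of class `hemisnet_lmm`: list with `coefficient` (the
#'   diagnosis fixed effect), `se`, `t`, `df` (residual fixed-effects
#'   degrees of freedom, n - p), `sigma2`, `lambda` (variance ratio),
#'   `n`, `n_cases`, `n_controls`, `n_excluded`, `variant`.
#' @export
fit_case_control_model <- function(outcome, subjects, variant = "main",
                                   global_thickness = NULL) {
  des <- build_design(subjects, variant, global_thickness)
  keep <- des$keep & is.finite(outcome)
  n_excl <- sum(!keep)
  if (n_excl > 0)
    message("fit_case_control_model: excluding ", n_excl,
            " subject(s) with missing outcome/age/sex")
  y <- outcome[keep]
  X <- des$X[keep, , drop = FALSE]
  grp <- factor(des$groups[keep])
  diag01 <- X[, des$pcol]
  check_model_inputs(y, X, grp, diag01)
  fit <- reml_fit_cpp(X, y, as.integer(grp) - 1L, nlevels(grp))
  structure(list(
    coefficient = fit$beta[des$pcol],
    se = fit$se[des$pcol],
    t = fit$t[des$pcol],
    df = fit$df,
    sigma2 = fit$sigma2,
    lambda = fit$lambda,
    beta = stats::setNames(as.numeric(fit$beta), colnames(des$X)),
    n = length(y),
    n_cases = sum(diag01 == 1),
    n_controls = sum(diag01 == 0),
    n_excluded = n_excl,
    variant = variant
  ), class = "hemisnet_lmm")
}

#' @export
print.hemisnet_lmm <- function(x, ...) {
  cat(sprintf(
    "mixed-model case-control fit (%s): coef = %.4g, t = %.3f, df = %d, n = %d (%d cases / %d controls)\n",
    x$variant, x$coefficient, x$t, x$df, x$n, x$n_cases, x$n_controls))
  invisible(x)
}

#' Cohen's d from a mixed-model t statistic
#'
#' Two-group conversion `d = t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))`
#' with `df` the residual degrees of freedom of the fixed-effects design.
#'
#' @param t Diagnosis t statistic.
#' @param n1,n2 Group sizes (cases, controls).
#' @param df Residual degrees of freedom (> 0).
#' @return Cohen's d, same sign as `t`.
#' @export
#' @examples
#' cohens_d_from_t(2, 50, 50, 96)  # ~0.408
cohens_d_from_t <- function(t, n1, n2, df) {
  if (any(df <= 0)) stop("df must be > 0")
  if (any(n1 < 1) || any(n2 < 1)) stop("group sizes must be >= 1")
  t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))
}

# Within-dataset (default) or global label permutations.
# Returns an n x n_perm matrix of permuted predictor columns.
make_permutations <- function(predictor, groups, n_perm, global = FALSE) {
  n <- length(predictor)
  idx_by_group <- if (global) list(seq_len(n)) else
    split(seq_len(n), groups)
  P <- matrix(NA_real_, n, n_perm)
  for (j in seq_len(n_perm)) {
    for (idx in idx_by_group)
      P[idx, j] <- predictor[idx[sample.int(length(idx))]]
  }
  P
}

# Shared permutation engine: same design for every outcome column of Y,
# identical permutations across columns. Returns observed t, permuted t
# matrix, empirical p, coefficient and model size per column.
lmm_permutation_test <- function(Y, subjects, variant = "main",
                                 n_perm = 1000L, rng_seed = 1L,
                                 global_thickness = NULL,
                                 predictor = NULL,
                                 global_permutation = FALSE,
                                 covariates = c("age", "sex")) {
  Y <- as.matrix(Y)
  des <- build_design(subjects, variant, global_thickness, predictor)
  keep <- des$keep & apply(is.finite(Y), 1, all)
  n_excl <- sum(!keep)
  if (n_excl > 0)
    message("permutation test: excluding ", n_excl,
            " subject(s) with missing outcome/covariates")
  Y <- Y[keep, , drop = FALSE]
  X <- des$X[keep, , drop = FALSE]
  drop_cols <- setdiff(c("age", "sex"), covariates)
  if (length(drop_cols)) X <- X[, setdiff(colnames(X), drop_cols),
                                drop = FALSE]
  grp <- factor(des$groups[keep])
  pred <- X[, des$pcol]
  for (j in seq_len(ncol(Y)))
    check_model_inputs(Y[, j], X, grp,
                       if (is.null(predictor)) pred else NULL)
  set.seed(as.integer(rng_seed))
  P <- make_permutations(pred, grp, n_perm, global = global_permutation)
  tmat <- reml_perm_t_cpp(X, Y, as.integer(grp) - 1L, nlevels(grp),
                          des$pcol - 1L, cbind(pred, P))
  t_obs <- tmat[1, ]
  t_perm <- tmat[-1, , drop = FALSE]
  fail <- colSums(!is.finite(t_perm))
  if (any(fail > 0.01 * n_perm))
    stop("mixed-model fit failed in more than 1% of permutations (",
         max(fail), " of ", n_perm, ")")
  p <- vapply(seq_len(ncol(Y)), function(j) {
    tp <- t_perm[, j]
    ok <- is.finite(tp)
    (1 + sum(abs(tp[ok]) >= abs(t_obs[j]))) / (1 + sum(ok))
  }, numeric(1))
  # coefficients from the observed fit
  coefs <- ses <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    f <- reml_fit_cpp(X, Y[, j], as.integer(grp) - 1L, nlevels(grp))
    coefs[j] <- f$beta[des$pcol]
    ses[j] <- f$se[des$pcol]
  }
  list(t_obs = t_obs, p = p, coefficient = coefs, se = ses,
       df = nrow(X) - ncol(X),
       n = nrow(X), n_cases = sum(pred == 1), n_controls = sum(pred == 0),
       n_excluded = n_excl)
}

#' Permutation p-value for the diagnosis effect
#'
#' Refits the mixed model under `n_perm` label-swap permutations of the
#' diagnosis labels (within dataset by default, preserving each dataset's
#' case/control count) and returns the two-tailed add-one empirical
#' p-value, `(1 + #permutations with |t| >= |t_obs|) / (1 + n_perm)`.
#' Deterministic given `rng_seed`.
#'
#' @inheritParams fit_case_control_model
#' @param n_perm Number of permutations (>= 1).
#' @param rng_seed Integer seed.
#' @param global_permutation Swap labels across the whole cohort instead of
#'   within dataset.
#' @return The empirical p-value, in `[1/(n_perm+1), 1]`, with attributes
#'   `t_obs` and `t_perm`.
#' @export
permutation_pvalue <- function(outcome, subjects, variant = "main",
                               n_perm = 1000L, rng_seed = 1L,
                               global_thickness = NULL,
                               global_permutation = FALSE) {
  stopifnot(n_perm >= 1L)
  res <- lmm_permutation_test(matrix(outcome, ncol = 1), subjects, variant,
                              n_perm, rng_seed, global_thickness,
                              global_permutation = global_permutation)
  structure(res$p, t_obs = res$t_obs, coefficient = res$coefficient)
}

#' Tiered multiple-testing adjustment
#'
#' `"hemisphere"`: Bonferroni over the 3 hemisphere-level metrics
#' (significant iff raw p < alpha / m). `"node"`: Benjamini-Hochberg over
#' the 34 nodes of one metric, significant iff adjusted p < `alpha`
#' (0.05/4 by default upstream, for the four node metrics). `"edge"`: BH
#' over the 33 edges of one seed at `alpha`. `"unilateral"` and
#' `"within_case"`: descriptive follow-ups, no correction.
#'
#' @param p Vector of p-values in (0, 1].
#' @param tier One of `"hemisphere"`, `"node"`, `"edge"`, `"unilateral"`,
#'   `"within_case"`.
#' @param alpha Significance threshold applied to the (adjusted) p-values;
#'   defaults per tier: 0.05 Bonferroni-divided at the hemisphere tier,
#'   0.05/4 at the node tier, 0.05 otherwise.
#' @return List with `p_adjusted` and logical `significant`.
#' @export
#' @examples
#' adjust_pvalues(c(0.02, 0.10, 0.04), "hemisphere")$significant
adjust_pvalues <- function(p,
                           tier = c("hemisphere", "node", "edge",
                                    "unilateral", "within_case"),
                           alpha = NULL) {
  tier <- match.arg(tier)
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  if (is.null(alpha))
    alpha <- switch(tier, hemisphere = 0.05, node = 0.05 / 4, 0.05)
  switch(tier,
    hemisphere = {
      padj <- pmin(1, p * length(p))
      list(p_adjusted = padj, significant = p < alpha / length(p))
    },
    node = ,
    edge = {
      padj <- stats::p.adjust(p, method = "BH")
      list(p_adjusted = padj, significant = padj < alpha)
    },
    {
      list(p_adjusted = p, significant = p < alpha)
    })
}
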