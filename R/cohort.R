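#' Assemble a cohort object
#'
#' A cohort bundles the per-subject regional thickness matrix with the
#' covariates table, index-aligned by subject. This is the container every
#' pipeline stage consumes.
#'
#' @param thickness Numeric matrix or data frame, one row per subject, with
#'   the 68 canonical columns from [region_columns()]. Extra columns are an
#'   error; row order defines subject order.
#' @param subjects Data frame with columns `subject_id`, `dataset_id`,
#'   `diagnosis` (`"case"`/`"control"`), `age` (years, > 0), `sex`
#'   (`"M"`/`"F"`), and optionally `ados_total`, `medication` (0/1), `iq`,
#'   `handedness` (`"L"`/`"R"`). Missing optional values are `NA`.
#' @return An object of class `hemisnet_cohort`: a list with elements
#'   `thickness` (matrix, rownames = subject IDs) and `subjects`.
#' @export
hemisnet_cohort <- function(thickness, subjects) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  req <- c("subject_id", "dataset_id", "diagnosis", "age", "sex")
  miss <- setdiff(req, names(subjects))
  if (length(miss))
    stop("covariates table is missing required column(s): ",
         paste(miss, collapse = ", "))
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$dataset_id <- as.character(subjects$dataset_id)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  if (!all(subjects$diagnosis %in% c("case", "control")))
    stop("diagnosis must be 'case' or 'control'")
  if (any(!is.finite(subjects$age)) || any(subjects$age <= 0))
    stop("age must be finite and > 0 for every subject")
  if (!all(subjects$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  for (opt in c("ados_total", "medication", "iq", "handedness"))
    if (!opt %in% names(subjects)) subjects[[opt]] <- NA

  thickness <- as.matrix(thickness)
  cols <- region_columns()
  miss <- setdiff(cols, colnames(thickness))
  if (length(miss))
    stop("thickness table is missing region column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(colnames(thickness), cols)
  if (length(extra))
    stop("unexpected thickness column(s): ", paste(extra, collapse = ", "))
  thickness <- thickness[, cols, drop = FALSE]
  if (nrow(thickness) != nrow(subjects))
    stop("thickness table has ", nrow(thickness), " rows but covariates ",
         nrow(subjects))
  storage.mode(thickness) <- "double"
  bad <- which(!is.finite(thickness) | thickness <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "non-positive or non-numeric thickness at row %d, column '%s'",
      bad[1, 1], cols[bad[1, 2]]))
  rownames(thickness) <- subjects$subject_id
  structure(list(thickness = thickness, subjects = subjects),
            class = "hemisnet_cohort")
}

#' @export
print.hemisnet_cohort <- function(x, ...) {
  tab <- table(x$subjects$diagnosis)
  cat(sprintf(
    "hemisnet cohort: %d subjects (%d cases, %d controls) in %d dataset(s)\n",
    nrow(x$subjects), tab[["case"]], tab[["control"]],
    length(unique(x$subjects$dataset_id))))
  invisible(x)
}

#' Read a cohort from thickness and covariates tables
#'
#' Both files are header-ed, tab-separated by default (comma via the config
#' flag), UTF-8. The thickness file must carry a `subject_id` column plus the
#' 68 canonical region columns; the covariates file the required covariate
#' columns. Subjects present in only one of the two files are rejected.
#'
#' @param thickness_path,covariates_path File paths.
#' @param comma Files are comma- rather than tab-separated.
#' @return A [hemisnet_cohort()].
#' @export
read_cohort <- function(thickness_path, covariates_path, comma = FALSE) {
  for (p in c(thickness_path, covariates_path))
    if (!file.exists(p)) stop("file not found: ", p)
  sep <- if (comma) "," else "\t"
  th <- utils::read.table(thickness_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  cv <- utils::read.table(covariates_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!"subject_id" %in% names(th))
    stop("thickness table is missing region column(s): subject_id")
  miss <- setdiff(region_columns(), names(th))
  if (length(miss))
    stop("thickness table is missing region column(s): ",
         paste(miss, collapse = ", "))
  only_th <- setdiff(th$subject_id, cv$subject_id)
  only_cv <- setdiff(cv$subject_id, th$subject_id)
  if (length(only_th) || length(only_cv))
    stop("subjects present in only one file: ",
         paste(c(only_th, only_cv), collapse = ", "))
  cv <- cv[match(th$subject_id, cv$subject_id), , drop = FALSE]
  mat <- th[, region_columns(), drop = FALSE]
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v))
      stop("non-numeric thickness in column '", names(mat)[j], "'")
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stop(sprintf(
        "non-positive or non-numeric thickness at row %d, column '%s'",
        bad[1], names(mat)[j]))
  }
  mat <- as.matrix(mat)
  rownames(mat) <- th$subject_id
  hemisnet_cohort(mat, cv)
}

#' Write a cohort to thickness and covariates tables
#'
#' Inverse of [read_cohort()]: full double precision is preserved so a
#' round trip reproduces the cohort exactly to at least 12 significant
#' digits.
#'
#' @param cohort A [hemisnet_cohort()].
#' @param thickness_path,covariates_path Output paths.
#' @inheritParams read_cohort
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, thickness_path, covariates_path,
                         comma = FALSE) {
  stopifnot(inherits(cohort, "hemisnet_cohort"))
  sep <- if (comma) "," else "\t"
  th <- data.frame(subject_id = rownames(cohort$thickness),
                   cohort$thickness, check.names = FALSE)
  utils::write.table(format(th, digits = 17, trim = TRUE, scientific = FALSE),
                     thickness_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$subjects, covariates_path, sep = sep,
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(c(thickness_path, covariates_path))
}

#' Write a results table
#'
#' Tab-separated with columns metric, node, coefficient, t, cohens_d,
#' p_empirical, p_adjusted, significant; hemisphere-level rows carry
#' `"hemisphere"` in the node column. Numeric fields are written at full
#' double precision so re-reading reproduces them exactly.
#'
#' @param results Data frame of test results as produced by
#'   [run_node_level_analysis()] and friends; must be non-empty.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(as.data.frame(results)) == 0)
    stop("`results` is empty; refusing to write an empty results file")
  results <- as.data.frame(results)
  out <- data.frame(
    metric = results$metric,
    node = ifelse(is.na(results$node), "hemisphere", results$node),
    coefficient = fmt17(results$coefficient),
    t = fmt17(results$t),
    cohens_d = fmt17(results$cohens_d),
    p_empirical = fmt17(results$p_empirical),
    p_adjusted = fmt17(results$p_adjusted),
    significant = results$significant,
    stringsAsFactors = FALSE
  )
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path File path.
#' @return Data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

fmt17 <- function(x) formatC(x, digits = 17, format = "g")
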