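#' Exclusion criteria for the SUA cohort
#'
#' A twin is flagged when it has gout, systemic lupus erythematosus,
#' eGFR below `egfr_min` (percent) or serum creatinine above
#' `creatinine_max` (mg/dL), or a missing phenotype; exclusion is
#' pairwise — the whole pair is dropped when either twin is flagged.
#'
#' @param egfr_min eGFR floor, percent. Default 60.
#' @param creatinine_max Creatinine ceiling, mg/dL. Default 1.4.
#' @return An object of class `exclusion_criteria`.
#' @export
exclusion_criteria <- function(egfr_min = 60, creatinine_max = 1.4) {
  stopifnot(egfr_min > 0, creatinine_max > 0)
  structure(list(egfr_min = egfr_min, creatinine_max = creatinine_max),
            class = "exclusion_criteria")
}

#' Apply pairwise exclusions to a twin cohort
#'
#' @param cohort A twin cohort data frame.
#' @param criteria An [exclusion_criteria()] object.
#' @return The retained cohort, with a `removal_log` attribute — a data
#'   frame of removed pairs and comma-separated reason codes
#'   (`gout`, `sle`, `low_egfr`, `high_creatinine`, `missing_phenotype`).
#' @export
apply_exclusions <- function(cohort, criteria = exclusion_criteria()) {
  flags <- cbind(
    gout = isTRUE_vec(cohort$gout),
    sle = isTRUE_vec(cohort$sle),
    low_egfr = !is.na(cohort$egfr) & cohort$egfr < criteria$egfr_min,
    high_creatinine = !is.na(cohort$creatinine) &
      cohort$creatinine > criteria$creatinine_max,
    missing_phenotype = is.na(cohort$sua))
  reasons <- lapply(split(as.data.frame(flags), cohort$pair_id),
                    function(f) colnames(flags)[colSums(f) > 0])
  drop <- vapply(reasons, function(r) length(r) > 0, logical(1))
  dropped_ids <- as.character(names(reasons)[drop])
  keep <- !(as.character(cohort$pair_id) %in% dropped_ids)
  out <- cohort[keep, ]
  rownames(out) <- NULL
  attr(out, "removal_log") <- data.frame(
    pair_id = dropped_ids,
    reason = vapply(reasons[drop], paste, character(1), collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Blom rank-based inverse-normal transform
#'
#' Maps values to normal scores `qnorm((r - 3/8) / (n + 1/4))` where `r`
#' is the rank among the `n` values; ties receive average ranks, so tied
#' values get identical scores.
#'
#' @param values Numeric vector with at least one finite value; `NA`s are
#'   propagated and do not enter the ranking.
#' @return Numeric vector of normal scores, same length as `values`.
#' @export
blom_transform <- function(values) {
  ok <- is.finite(values)
  if (!any(ok)) stop("blom_transform needs at least one finite value")
  n <- sum(ok)
  r <- rank(values[ok], ties.method = "average")
  if (n > 1 && length(unique(values[ok])) == 1L)
    warning("all values identical; Blom scores are all 0")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Residualize a phenotype on covariates by ordinary least squares
#'
#' Regresses `values` on an intercept plus the covariate columns and
#' returns the residuals (zero mean by construction). Used as the
#' pre-adjustment path for the twin correlations; the FIML model instead
#' carries covariates in its means model.
#'
#' @param values Numeric response vector.
#' @param covariate_matrix Numeric matrix or data frame, rows aligned
#'   with `values`. An intercept column is added automatically.
#' @return Residual vector.
#' @export
adjust_covariates <- function(values, covariate_matrix) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covariate_matrix))
  if (nrow(X) != length(values)) stop("rows of covariates must align")
  if (qr(X)$rank < ncol(X)) stop("covariate design is rank-deficient")
  stats::lm.fit(X, values)$residuals
}
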