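#' Phenotype summaries overall and by sex
#'
#' Median and 2.5th/97.5th percentiles (the "95% range") of the
#' phenotype, overall and within each sex.
#'
#' @param cohort A twin cohort data frame.
#' @return Data frame with columns `stratum`, `n`, `median`, `p2.5`,
#'   `p97.5`.
#' @export
describe_phenotype <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort")
  one <- function(label, x) {
    q <- stats::quantile(x, c(0.5, 0.025, 0.975), na.rm = TRUE, names = FALSE)
    data.frame(stratum = label, n = sum(!is.na(x)),
               median = q[1], p2.5 = q[2], p97.5 = q[3],
               stringsAsFactors = FALSE)
  }
  rbind(one("all", cohort$sua),
        one("female", cohort$sua[cohort$sex == "F"]),
        one("male", cohort$sua[cohort$sex == "M"]))
}

fisher_ci <- function(r, n, level = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Twin-pair Pearson correlation with Fisher confidence interval
#'
#' Pearson product-moment correlation over (twin 1, twin 2) phenotype
#' pairs, with a 95% CI from the Fisher z transform using standard error
#' `1/sqrt(n_pairs - 3)`.
#'
#' @param pair_values Two-column numeric matrix (or data frame), one row
#'   per pair: twin 1 and twin 2 values.
#' @param group Optional group label carried into the result.
#' @param level Confidence level, default 0.95.
#' @return Data frame with `group`, `r`, `n_pairs`, `ci_low`, `ci_high`.
#' @export
twin_correlation <- function(pair_values, group = NA_character_,
                             level = 0.95) {
  pv <- as.matrix(pair_values)
  pv <- pv[stats::complete.cases(pv), , drop = FALSE]
  n <- nrow(pv)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(pv[, 1]) == 0 || stats::sd(pv[, 2]) == 0)
    stop("zero variance in a twin series")
  r <- stats::cor(pv[, 1], pv[, 2])
  ci <- fisher_ci(r, n, level)
  data.frame(group = group, r = r, n_pairs = n,
             ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
}

#' Zygosity-stratified and pooled twin correlations
#'
#' Computes the per-group correlations plus pooled MZ and pooled DZ
#' correlations on a (typically residualized) phenotype column. Pairs are
#' oriented as stored — twin 1 versus twin 2, with DZos pairs
#' female-first — matching single-entry Pearson correlation.
#'
#' @param cohort A twin cohort data frame.
#' @param value_col Column holding the phenotype to correlate
#'   (default `"sua"`).
#' @return Data frame of [twin_correlation()] rows: one per non-empty
#'   group, plus `"MZ"` and `"DZ"` pooled rows.
#' @export
cohort_correlations <- function(cohort, value_col = "sua") {
  pr <- cohort_pairs(cohort)
  Y <- cbind(pr$t1[[value_col]], pr$t2[[value_col]])
  res <- list()
  for (g in .twin_groups) {
    sel <- pr$group == g
    if (sum(sel) >= 4)
      res[[g]] <- twin_correlation(Y[sel, , drop = FALSE], g)
  }
  mz <- pr$group %in% c("MZm", "MZf")
  dz <- pr$group %in% c("DZm", "DZf", "DZos")
  if (sum(mz) >= 4) res[["MZ"]] <- twin_correlation(Y[mz, , drop = FALSE], "MZ")
  if (sum(dz) >= 4) res[["DZ"]] <- twin_correlation(Y[dz, , drop = FALSE], "DZ")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pooled dizygotic twin correlation
#'
#' Correlation over all DZ pairs combined (same-sex and opposite-sex),
#' with opposite-sex pairs oriented female-first.
#'
#' @param cohort A twin cohort data frame (only DZ groups are used).
#' @param value_col Phenotype column, default `"sua"`.
#' @return A [twin_correlation()] row with group `"DZ"`.
#' @export
pool_dz_correlation <- function(cohort, value_col = "sua") {
  pr <- cohort_pairs(cohort)
  dz <- pr$group %in% c("DZm", "DZf", "DZos")
  if (!any(dz)) stop("no DZ pairs in cohort")
  Y <- cbind(pr$t1[[value_col]], pr$t2[[value_col]])[dz, , drop = FALSE]
  twin_correlation(Y, "DZ")
}
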