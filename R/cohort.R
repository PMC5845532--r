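#' Twin-pair group sizes
#'
#' Counts of complete twin pairs in the five zygosity-sex groups of the
#' classical twin design. Defaults are the group sizes of the SUA twin
#' cohort the package emulates: 240 MZ pairs (114 male, 126 female) and
#' 139 DZ pairs (41 male, 39 female, 59 opposite-sex), 379 pairs in all.
#'
#' @param n_mz_m,n_mz_f Number of male / female monozygotic pairs.
#' @param n_dz_m,n_dz_f Number of male / female same-sex dizygotic pairs.
#' @param n_dz_os Number of opposite-sex dizygotic pairs.
#' @return An object of class `group_sizes` (a named list of counts).
#' @export
group_sizes <- function(n_mz_m = 114, n_mz_f = 126,
                        n_dz_m = 41, n_dz_f = 39, n_dz_os = 59) {
  counts <- c(n_mz_m = n_mz_m, n_mz_f = n_mz_f,
              n_dz_m = n_dz_m, n_dz_f = n_dz_f, n_dz_os = n_dz_os)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("group sizes must be non-negative integers")
  structure(as.list(counts), class = "group_sizes")
}

#' @export
print.group_sizes <- function(x, ...) {
  cat("Twin-pair group sizes:\n")
  print(unlist(x))
  cat("total pairs:", sum(unlist(x)), "\n")
  invisible(x)
}

#' Sex-limitation variance-component parameters
#'
#' Path coefficients of the general sex-limitation ACE model, in
#' phenotype-SD units (the variance contributed by a path is its square).
#' Females have paths `a_f`, `c_f`, `e_f`; males have `a_m`, `c_m`, `e_m`
#' plus an optional male-specific additive genetic path `am_prime`.
#'
#' @param a_f,c_f,e_f Female additive genetic, shared environmental and
#'   unique environmental paths.
#' @param a_m,c_m,e_m Male counterparts.
#' @param am_prime Male-specific additive genetic path (0 in the
#'   common-effects sub-models).
#' @return An object of class `sexlim_parameters`.
#' @export
sexlim_parameters <- function(a_f, c_f, e_f, a_m, c_m, e_m, am_prime = 0) {
  p <- c(a_f = a_f, c_f = c_f, e_f = e_f,
         a_m = a_m, c_m = c_m, e_m = e_m, am_prime = am_prime)
  if (any(!is.finite(p))) stop("all path coefficients must be finite")
  if (any(p < 0)) stop("path coefficients must be >= 0 (sign convention)")
  if (p[["e_f"]] <= 0 || p[["e_m"]] <= 0)
    stop("unique environmental paths e_f and e_m must be positive")
  structure(as.list(p), class = "sexlim_parameters")
}

#' Sex-limitation parameters from standardized variance shares
#'
#' Convenience constructor taking per-sex standardized components (percent
#' or proportions of total variance) and converting them to path
#' coefficients on a unit-variance scale: path = sqrt(share).
#'
#' @param shares_f,shares_m Numeric length-3 vectors `(A, C, E)` per sex,
#'   either percentages summing to 100 or proportions summing to 1.
#' @param am_prime_share Male-specific additive share (same scale), taken
#'   out of the male A share if `fold = TRUE` (default) or added on top.
#' @param fold If `TRUE`, `am_prime_share` is carved out of `shares_m[1]`
#'   so the male total stays 1.
#' @return A `sexlim_parameters` object with unit total variance per sex.
#' @export
sexlim_from_shares <- function(shares_f, shares_m, am_prime_share = 0,
                               fold = TRUE) {
  norm <- function(x) if (sum(x) > 3) x / 100 else x
  f <- norm(shares_f); m <- norm(shares_m)
  amp <- if (am_prime_share > 1) am_prime_share / 100 else am_prime_share
  if (abs(sum(f) - 1) > 0.02 || abs(sum(m) + (!fold) * amp - 1) > 0.02)
    stop("shares must sum to 1 (or 100%) per sex")
  a_m2 <- if (fold) max(m[1] - amp, 0) else m[1]
  sexlim_parameters(a_f = sqrt(f[1]), c_f = sqrt(f[2]), e_f = sqrt(f[3]),
                    a_m = sqrt(a_m2), c_m = sqrt(m[2]), e_m = sqrt(m[3]),
                    am_prime = sqrt(amp))
}

.twin_groups <- c("MZm", "MZf", "DZm", "DZf", "DZos")

#' Validate a twin cohort table
#'
#' A twin cohort is a data frame with one row per twin: columns `pair_id`,
#' `group` (MZm/MZf/DZm/DZf/DZos), `twin` (1 or 2), `sex` ("F"/"M"),
#' `age`, `bmi`, `sua` (serum uric acid, umol/L) and the exclusion inputs
#' `gout`, `sle` (logical) and `egfr`, `creatinine` (numeric). By
#' convention, twin 1 of an opposite-sex DZ pair is the female.
#'
#' @param cohort A data frame as above.
#' @return The cohort, invisibly, after checks.
#' @export
validate_cohort <- function(cohort) {
  need <- c("pair_id", "group", "twin", "sex", "age", "bmi", "sua")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  if (!all(cohort$group %in% .twin_groups))
    stop("unknown group label(s): ",
         paste(setdiff(unique(cohort$group), .twin_groups), collapse = ", "))
  tab <- table(cohort$pair_id)
  if (any(tab != 2)) stop("every pair_id must appear exactly twice")
  sx <- split(cohort$sex, cohort$pair_id)
  gp <- vapply(split(as.character(cohort$group), cohort$pair_id),
               `[`, character(1), 1)
  same <- vapply(sx, function(s) s[1] == s[2], logical(1))
  if (any(gp != "DZos" & !same))
    stop("same-sex groups must have identical sex within pair")
  if (any(gp == "DZos" & same))
    stop("DZos pairs must have one female and one male twin")
  os <- cohort[cohort$group == "DZos", ]
  if (nrow(os) && any(os$sex[os$twin == 1] != "F"))
    stop("DZos convention violated: twin 1 must be the female")
  invisible(cohort)
}

# wide (one row per pair) view used by correlations and FIML
cohort_pairs <- function(cohort) {
  ord <- order(cohort$pair_id, cohort$twin)
  co <- cohort[ord, ]
  t1 <- co[co$twin == 1, ]
  t2 <- co[co$twin == 2, ]
  stopifnot(all(t1$pair_id == t2$pair_id))
  list(t1 = t1, t2 = t2,
       group = as.character(t1$group), pair_id = t1$pair_id)
}
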