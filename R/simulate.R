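#' Covariate and scale specification for the cohort generator
#'
#' Distributions and linear effect sizes used when simulating twin
#' phenotypes. Age is drawn uniformly on `age_range` and shared within a
#' pair; BMI is Normal per twin. The phenotype mean for a twin is
#' `intercept_sex + beta_age*(age-50) + beta_bmi*(bmi-bmi_mean) +
#' beta_age_sex*(age-50)*male`, and the ACE deviation is scaled by `sd`
#' (umol/L per phenotype-SD unit). eGFR, creatinine and the gout/SLE flags
#' feed the exclusion stage; with the default rates of 0 the generated
#' cohort passes exclusions untouched.
#'
#' @param age_range Length-2 numeric, years. Default c(41, 69), the 95%
#'   age range of the cohort emulated.
#' @param bmi_mean,bmi_sd BMI distribution, kg/m^2.
#' @param intercept_f,intercept_m Sex-specific phenotype means, umol/L.
#' @param beta_age,beta_bmi,beta_age_sex Linear covariate effects
#'   (umol/L per year, per kg/m^2, and per year extra in males).
#' @param sd Scale of the standardized ACE deviation, umol/L.
#' @param egfr_mean,egfr_sd,creatinine_mean,creatinine_sd Lab-value
#'   distributions (percent of normal; mg/dL).
#' @param p_gout,p_sle Per-twin probabilities of the exclusion flags.
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(age_range = c(41, 69), bmi_mean = 24.5,
                           bmi_sd = 3.2, intercept_f = 226,
                           intercept_m = 298, beta_age = 0.8,
                           beta_bmi = 3, beta_age_sex = 0.4, sd = 55,
                           egfr_mean = 90, egfr_sd = 10,
                           creatinine_mean = 0.9, creatinine_sd = 0.15,
                           p_gout = 0, p_sle = 0) {
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2],
            bmi_sd > 0, sd > 0, p_gout >= 0, p_gout <= 1,
            p_sle >= 0, p_sle <= 1)
  structure(list(age_range = age_range, bmi_mean = bmi_mean,
                 bmi_sd = bmi_sd, intercept_f = intercept_f,
                 intercept_m = intercept_m, beta_age = beta_age,
                 beta_bmi = beta_bmi, beta_age_sex = beta_age_sex,
                 sd = sd, egfr_mean = egfr_mean, egfr_sd = egfr_sd,
                 creatinine_mean = creatinine_mean,
                 creatinine_sd = creatinine_sd,
                 p_gout = p_gout, p_sle = p_sle),
            class = "covariate_spec")
}

# sexes of (twin1, twin2) for each group; DZos is female-first by convention
.group_sexes <- list(MZm = c("M", "M"), MZf = c("F", "F"),
                     DZm = c("M", "M"), DZf = c("F", "F"),
                     DZos = c("F", "M"))

#' Simulate a five-group twin cohort under the sex-limitation ACE model
#'
#' Generates pairs in each zygosity-sex group with phenotype
#' `mean(covariates) + sd * (a*A + c*C + e*E [+ am'*Am' in males])`.
#' The additive factor A is shared fully within MZ pairs and correlated
#' 0.5 within DZ pairs (including opposite-sex pairs); C is shared fully
#' within every pair; E is independent per twin. The male-specific
#' additive factor Am' is fully shared in MZ-male pairs, correlated 0.5
#' in DZ-male pairs, and contributes nothing to the opposite-sex
#' covariance (it still adds am'^2 to the male twin's variance).
#'
#' @param params A [sexlim_parameters()] object.
#' @param sizes A [group_sizes()] object.
#' @param covariates A [covariate_spec()] object.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A twin cohort data frame (see [validate_cohort()]).
#' @export
simulate_twin_cohort <- function(params, sizes = group_sizes(),
                                 covariates = covariate_spec(),
                                 seed = 1L) {
  if (!inherits(params, "sexlim_parameters"))
    params <- do.call(sexlim_parameters, as.list(params))
  if (!inherits(sizes, "group_sizes")) sizes <- do.call(group_sizes, as.list(sizes))
  set.seed(seed)
  cs <- covariates
  n_by_group <- c(MZm = sizes$n_mz_m, MZf = sizes$n_mz_f,
                  DZm = sizes$n_dz_m, DZf = sizes$n_dz_f,
                  DZos = sizes$n_dz_os)
  out <- vector("list", length(n_by_group))
  pair_offset <- 0L
  for (g in names(n_by_group)) {
    n <- n_by_group[[g]]
    if (n == 0L) { out[[g]] <- NULL; next }
    sexes <- .group_sexes[[g]]
    mz <- g %in% c("MZm", "MZf")

    # additive genetic factor, r = 1 (MZ) or 0.5 (any DZ)
    if (mz) {
      A1 <- A2 <- rnorm(n)
    } else {
      Ac <- rnorm(n)
      A1 <- sqrt(0.5) * Ac + sqrt(0.5) * rnorm(n)
      A2 <- sqrt(0.5) * Ac + sqrt(0.5) * rnorm(n)
    }
    C1 <- C2 <- rnorm(n)                       # shared environment
    E1 <- rnorm(n); E2 <- rnorm(n)             # unique environment
    # male-specific additive factor
    Am <- switch(g,
      MZm = { z <- rnorm(n); cbind(z, z) },
      DZm = { zc <- rnorm(n)
              cbind(sqrt(0.5) * zc + sqrt(0.5) * rnorm(n),
                    sqrt(0.5) * zc + sqrt(0.5) * rnorm(n)) },
      DZos = cbind(rep(0, n), rnorm(n)),       # male is twin 2; no cov share
      cbind(rep(0, n), rep(0, n)))

    path <- function(sex, which)
      params[[paste0(which, if (sex == "F") "_f" else "_m")]]
    dev <- function(tw) {
      s <- sexes[tw]
      A <- if (tw == 1) A1 else A2
      C <- if (tw == 1) C1 else C2
      E <- if (tw == 1) E1 else E2
      d <- path(s, "a") * A + path(s, "c") * C + path(s, "e") * E
      if (s == "M") d <- d + params$am_prime * Am[, tw]
      d
    }

    age <- runif(n, cs$age_range[1], cs$age_range[2])  # shared within pair
    mk_twin <- function(tw) {
      s <- sexes[tw]
      bmi <- rnorm(n, cs$bmi_mean, cs$bmi_sd)
      mu <- (if (s == "F") cs$intercept_f else cs$intercept_m) +
        cs$beta_age * (age - 50) + cs$beta_bmi * (bmi - cs$bmi_mean) +
        (s == "M") * cs$beta_age_sex * (age - 50)
      data.frame(pair_id = pair_offset + seq_len(n), group = g, twin = tw,
                 sex = s, age = age, bmi = bmi,
                 sua = mu + cs$sd * dev(tw),
                 gout = runif(n) < cs$p_gout, sle = runif(n) < cs$p_sle,
                 egfr = rnorm(n, cs$egfr_mean, cs$egfr_sd),
                 creatinine = rnorm(n, cs$creatinine_mean, cs$creatinine_sd),
                 stringsAsFactors = FALSE)
    }
    out[[g]] <- rbind(mk_twin(1), mk_twin(2))
    pair_offset <- pair_offset + n
  }
  cohort <- do.call(rbind, out)
  cohort <- cohort[order(cohort$pair_id, cohort$twin), ]
  rownames(cohort) <- NULL
  validate_cohort(cohort)
  cohort
}

#' Simulate genotypes for DZ sibling pairs
#'
#' Per SNP, a minor-allele frequency is drawn uniformly on
#' `[maf_low, maf_high]`, four parental alleles are drawn Bernoulli(MAF),
#' and each sibling inherits one paternal and one maternal allele chosen
#' independently, so the pair shares 0/1/2 parental alleles identical by
#' descent with probabilities 1/4, 1/2, 1/4. Missing entries are then
#' injected independently at `missing_rate`.
#'
#' @param n_pairs Number of sibling (DZ) pairs.
#' @param n_snps Number of SNPs.
#' @param maf_low,maf_high Bounds of the uniform MAF distribution; pass
#'   `maf_low == maf_high` for a fixed MAF.
#' @param missing_rate Per-entry missingness probability.
#' @param pair_ids Optional pair identifiers (length `n_pairs`) used to
#'   label rows as `<pair_id>_<twin>`; default `1:n_pairs`.
#' @param seed Integer seed.
#' @return A list with `genotypes` (2*n_pairs x n_snps integer matrix in
#'   \{0,1,2,NA\}, rows pair-major: twin 1 then twin 2 of pair 1, ...),
#'   `meta` (data frame: snp, chrom, pos, ref, alt, maf), and the realized
#'   IBD states as `attr(genotypes, "ibd")` (n_pairs x n_snps).
#' @export
simulate_dz_genotypes <- function(n_pairs, n_snps, maf_low = 0.05,
                                  maf_high = 0.5, missing_rate = 0,
                                  pair_ids = NULL, seed = 1L) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low <= maf_high <= 0.5")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (is.null(pair_ids)) pair_ids <- seq_len(n_pairs)
  stopifnot(length(pair_ids) == n_pairs)
  set.seed(seed)

  maf <- runif(n_snps, maf_low, maf_high)
  draw <- function() matrix(rbinom(n_pairs * n_snps, 1L,
                                   rep(maf, each = n_pairs)),
                            n_pairs, n_snps)
  f1 <- draw(); f2 <- draw(); m1 <- draw(); m2 <- draw()
  pick <- function() matrix(sample.int(2L, n_pairs * n_snps, replace = TRUE),
                            n_pairs, n_snps)
  i1p <- pick(); i2p <- pick(); i1m <- pick(); i2m <- pick()
  sel <- function(a1, a2, idx) ifelse(idx == 1L, a1, a2)
  g1 <- sel(f1, f2, i1p) + sel(m1, m2, i1m)
  g2 <- sel(f1, f2, i2p) + sel(m1, m2, i2m)
  ibd <- (i1p == i2p) + (i1m == i2m)

  geno <- matrix(NA_integer_, 2L * n_pairs, n_snps)
  geno[seq(1L, 2L * n_pairs, by = 2L), ] <- g1
  geno[seq(2L, 2L * n_pairs, by = 2L), ] <- g2
  if (missing_rate > 0)
    geno[runif(length(geno)) < missing_rate] <- NA_integer_
  rownames(geno) <- paste(rep(pair_ids, each = 2L), rep(1:2, n_pairs),
                          sep = "_")

  # spread SNPs over up to 22 autosomes, positions increasing within each
  n_chr <- min(22L, n_snps)
  chrom <- sort(rep_len(seq_len(n_chr), n_snps))
  pos <- integer(n_snps)
  for (ch in seq_len(n_chr)) {
    idx <- which(chrom == ch)
    pos[idx] <- cumsum(sample(500:50000, length(idx), replace = TRUE))
  }
  meta <- data.frame(snp = sprintf("snp%06d", seq_len(n_snps)),
                     chrom = chrom, pos = pos,
                     ref = "A", alt = "G", maf = maf,
                     stringsAsFactors = FALSE)
  colnames(geno) <- meta$snp
  attr(geno, "ibd") <- ibd
  list(genotypes = geno, meta = meta)
}

#' Add a single-SNP additive effect to a cohort's phenotype
#'
#' Increments each genotyped individual's phenotype by `beta` times the
#' minor-allele count at one SNP; all other fields are unchanged.
#' Genotype rows map to cohort members through their `<pair_id>_<twin>`
#' row names.
#'
#' @param cohort A twin cohort data frame.
#' @param genotypes Genotype matrix with `<pair_id>_<twin>` row names.
#' @param snp_index Column index of the SNP to spike.
#' @param beta Effect size, phenotype units per minor allele. Missing
#'   genotypes contribute no increment.
#' @return The modified cohort.
#' @export
spike_snp_effect <- function(cohort, genotypes, snp_index, beta) {
  stopifnot(snp_index >= 1, snp_index <= ncol(genotypes))
  ids <- paste(cohort$pair_id, cohort$twin, sep = "_")
  hit <- match(rownames(genotypes), ids)
  if (anyNA(hit))
    stop("genotyped individuals not in cohort: ",
         paste(utils::head(rownames(genotypes)[is.na(hit)]), collapse = ", "))
  g <- genotypes[, snp_index]
  g[is.na(g)] <- 0
  cohort$sua[hit] <- cohort$sua[hit] + beta * g
  cohort
}
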