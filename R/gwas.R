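#' SNP quality-control thresholds
#'
#' Defaults follow the published filter set: call rate >= 0.98, locus
#' missingness <= 0.05, Hardy-Weinberg exact p >= 1e-4, minor allele
#' frequency >= 0.05. Call rate and missingness are both applied
#' literally even though they overlap.
#'
#' @param min_call_rate,max_missing,hwe_p_floor,maf_floor Thresholds.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.98, max_missing = 0.05,
                          hwe_p_floor = 1e-4, maf_floor = 0.05) {
  th <- c(min_call_rate, max_missing, hwe_p_floor, maf_floor)
  if (any(th <= 0) || any(th >= 1)) stop("thresholds must lie in (0, 1)")
  structure(list(min_call_rate = min_call_rate, max_missing = max_missing,
                 hwe_p_floor = hwe_p_floor, maf_floor = maf_floor),
            class = "qc_thresholds")
}

# orient each SNP so the counted allele is the minor one (freq <= 0.5)
orient_minor <- function(genotypes) {
  af <- colMeans(genotypes, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  genotypes[, flip] <- 2L - genotypes[, flip]
  attr(genotypes, "flipped") <- flip
  genotypes
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the allele counts, the p-value is the
#' sum of probabilities of all heterozygote counts no more probable than
#' the observed one, under the hypergeometric-type null of random union
#' of gametes.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no individuals")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  hets <- seq.int(rare %% 2L, rare, by = 2L)  # attainable het counts
  # log P(n_het | allele counts), Levene/Haldane distribution
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((na - hets) / 2 + 1) +
    hets * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' SNP quality control
#'
#' Keeps a SNP iff call rate >= `min_call_rate`, missingness <=
#' `max_missing`, Hardy-Weinberg exact p >= `hwe_p_floor`, and minor
#' allele frequency >= `maf_floor`. MAF is computed on non-missing
#' entries after minor-allele orientation. When `pair_ids` is given
#' (twin data), the HWE test uses one randomly chosen twin per pair
#' (fixed `seed`) so within-pair dependence does not inflate the test.
#'
#' @param genotypes Individuals x SNPs matrix in \{0,1,2,NA\}.
#' @param meta SNP metadata data frame (same SNP order), or `NULL`.
#' @param thresholds A [qc_thresholds()] object.
#' @param pair_ids Optional per-individual pair identifiers.
#' @param seed Seed for the one-twin-per-pair choice.
#' @return List with `keep` (logical per SNP) and `report` (data frame:
#'   snp, call_rate, missing, maf, hwe_p, keep, reason).
#' @export
snp_qc <- function(genotypes, meta = NULL, thresholds = qc_thresholds(),
                   pair_ids = NULL, seed = 1L) {
  if (!ncol(genotypes) || !nrow(genotypes)) stop("empty genotype matrix")
  n <- nrow(genotypes)
  n_obs <- colSums(!is.na(genotypes))
  call_rate <- n_obs / n
  missing <- 1 - call_rate
  g <- orient_minor(genotypes)
  maf <- colMeans(g, na.rm = TRUE) / 2
  maf[n_obs == 0] <- 0

  hwe_rows <- seq_len(n)
  if (!is.null(pair_ids)) {
    set.seed(seed)
    hwe_rows <- vapply(split(seq_len(n), pair_ids),
                       function(ix) if (length(ix) == 1L) ix
                                    else ix[sample.int(length(ix), 1L)],
                       integer(1))
  }
  gh <- g[hwe_rows, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(gh)), function(j) {
    x <- gh[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, numeric(1))

  keep <- call_rate >= thresholds$min_call_rate &
    missing <= thresholds$max_missing &
    hwe_p >= thresholds$hwe_p_floor &
    maf >= thresholds$maf_floor
  reason <- character(ncol(genotypes))
  reason[call_rate < thresholds$min_call_rate] <- "call_rate"
  reason[missing > thresholds$max_missing] <-
    paste0(reason[missing > thresholds$max_missing], ",missing")
  reason[hwe_p < thresholds$hwe_p_floor] <-
    paste0(reason[hwe_p < thresholds$hwe_p_floor], ",hwe")
  reason[maf < thresholds$maf_floor] <-
    paste0(reason[maf < thresholds$maf_floor], ",maf")
  reason <- sub("^,", "", reason)
  snp_names <- if (!is.null(meta)) meta$snp else colnames(genotypes)
  if (is.null(snp_names)) snp_names <- sprintf("snp%06d", seq_len(ncol(genotypes)))
  report <- data.frame(
    snp = snp_names,
    call_rate = call_rate, missing = missing, maf = maf, hwe_p = hwe_p,
    keep = keep, reason = reason, row.names = NULL,
    stringsAsFactors = FALSE)
  list(keep = keep, report = report)
}

#' Genetic relationship matrix
#'
#' Centered-and-scaled genotype cross-product averaged over SNPs
#' (GCTA-style): `G = Z Z' / m` with `Z_ij = (g_ij - 2p_j) /
#' sqrt(2 p_j (1 - p_j))`. Missing entries are mean-imputed per SNP.
#'
#' @param genotypes Individuals x SNPs matrix in \{0,1,2,NA\};
#'   zero-variance (monomorphic) SNPs must be excluded first.
#' @return Symmetric n x n relatedness matrix.
#' @export
compute_grm <- function(genotypes) {
  if (nrow(genotypes) < 2 || ncol(genotypes) < 1)
    stop("need >= 2 individuals and >= 1 SNP")
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("zero-variance SNPs must be excluded before the GRM")
  Z <- sweep(genotypes, 2, 2 * p)
  Z[is.na(Z)] <- 0            # mean imputation after centering
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(Z) / ncol(Z)
  (G + t(G)) / 2
}

#' Top principal components of a relatedness matrix
#'
#' Eigenvectors of the `k` largest eigenvalues, returned as orthonormal
#' score columns.
#'
#' @param grm Symmetric relatedness matrix.
#' @param k Number of components (default 5).
#' @return n x k matrix of scores (0 columns when `k = 0`).
#' @export
genotype_pcs <- function(grm, k = 5) {
  stopifnot(isSymmetric(unname(grm), tol = 1e-8))
  if (k == 0) return(matrix(numeric(0), nrow(grm), 0))
  ev <- eigen(grm, symmetric = TRUE)
  if (k > sum(ev$values > 1e-10)) stop("k exceeds the rank of the GRM")
  ev$vectors[, seq_len(k), drop = FALSE]
}

#' Mixed-model single-SNP association scan
#'
#' Single-random-effect linear mixed model `y = W alpha + x beta + u + e`
#' with `cov(u) = sigma_g^2 * GRM`. The GRM is eigendecomposed once, the
#' variance ratio `lambda = sigma_g^2 / sigma_e^2` is profiled by
#' one-dimensional restricted maximum likelihood on the null
#' (covariates-only) model over a log-spaced range [1e-5, 1e5], and
#' each SNP is then tested by a Wald test under generalized least
#' squares with the fitted weights. REML is the default because plain
#' ML degenerates when the GRM is singular and its null space overlaps
#' the covariate span (the residual variance collapses to zero at the
#' boundary); an ML switch is provided. When the profile pushes the
#' genetic variance to the boundary the weights are uniform and every
#' test reduces exactly to OLS.
#'
#' @param genotypes Individuals x SNPs matrix in \{0,1,2,NA\}; missing
#'   entries are mean-imputed, alleles re-oriented to minor.
#' @param phenotype Numeric response vector.
#' @param covariates Covariate matrix (intercept included by caller, or
#'   added here when absent).
#' @param grm Relatedness matrix from [compute_grm()].
#' @param reml Use REML (default) or plain ML for the variance ratio
#'   profile.
#' @return List with `assoc` (data frame: snp, beta, se, wald, p),
#'   `lambda_ratio` (fitted variance ratio) and `loglik` of the null.
#' @export
lmm_assoc <- function(genotypes, phenotype, covariates, grm,
                      reml = TRUE) {
  n <- length(phenotype)
  stopifnot(nrow(genotypes) == n, nrow(grm) == n)
  W <- as.matrix(covariates)
  if (!any(apply(W, 2, function(x) all(x == x[1]) && x[1] != 0)))
    W <- cbind(`(Intercept)` = 1, W)
  g <- orient_minor(genotypes)
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]

  ev <- eigen(grm, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  U <- ev$vectors
  yr <- drop(crossprod(U, phenotype))
  Wr <- crossprod(U, W)
  q <- ncol(Wr)

  nll <- function(log10_lam) {
    lam <- 10^log10_lam
    v <- lam * d + 1
    sw <- 1 / sqrt(v)
    Wt <- Wr * sw; yt <- yr * sw
    qrW <- qr(Wt)
    if (qrW$rank < q) return(.BARRIER)
    r <- qr.resid(qrW, yt)
    rss <- sum(r^2)
    if (reml) {
      s2 <- rss / (n - q)
      0.5 * ((n - q) * log(2 * pi * s2) + sum(log(v)) +
               determinant(crossprod(Wt), logarithm = TRUE)$modulus +
               (n - q))
    } else {
      s2 <- rss / n
      0.5 * (n * log(2 * pi * s2) + sum(log(v)) + n)
    }
  }
  # The profiled ML can be degenerate at lambda -> Inf when the GRM is
  # singular and its null space overlaps the covariate span (sigma_e^2
  # collapses to 0 there), so scan a coarse grid, prefer the best
  # interior local minimum, and refine it by one-dimensional search;
  # a boundary is accepted only when the profile is monotone.
  grid <- seq(-5, 5, by = 0.5)
  vals <- vapply(grid, nll, numeric(1))
  ng <- length(grid)
  interior <- which(vals[2:(ng - 1)] <= vals[1:(ng - 2)] &
                      vals[2:(ng - 1)] <= vals[3:ng]) + 1L
  i <- if (length(interior)) interior[which.min(vals[interior])]
       else which.min(vals)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, ng)]
  opt <- stats::optimize(nll, c(lo, hi), tol = 1e-6)
  lam <- 10^opt$minimum
  if (opt$objective > vals[i]) lam <- 10^grid[i]
  if (log10(lam) <= -5 + 1e-4) lam <- 0   # boundary: plain OLS

  v <- lam * d + 1
  sw <- 1 / sqrt(v)
  Wt <- Wr * sw
  yt <- yr * sw
  Gt <- crossprod(U, g) * sw
  qrW <- qr(Wt)
  if (qrW$rank < ncol(Wt)) stop("singular rotated covariate design")
  yres <- qr.resid(qrW, yt)
  Eres <- qr.resid(qrW, Gt)
  exx <- colSums(Eres^2)
  exy <- drop(crossprod(Eres, yres))
  beta <- exy / exx
  dfres <- n - ncol(Wt) - 1
  rss <- pmax(sum(yres^2) - beta^2 * exx, 0)
  se <- sqrt(rss / dfres / exx)
  wald <- (beta / se)^2
  p <- stats::pchisq(wald, 1, lower.tail = FALSE)
  assoc <- data.frame(
    snp = if (!is.null(colnames(genotypes))) colnames(genotypes)
          else sprintf("snp%06d", seq_len(ncol(genotypes))),
    beta = beta, se = se, wald = wald, p = p,
    row.names = NULL, stringsAsFactors = FALSE)
  list(assoc = assoc, lambda_ratio = lam, loglik = -opt$objective)
}

#' Genomic inflation factor
#'
#' `lambda = median(Wald statistics) / qchisq(0.5, 1)` (null median
#' 0.4549). Values near 1 indicate no systematic inflation.
#'
#' @param wald_statistics Numeric vector of 1-df chi-square statistics.
#' @param digits Rounding of the reported value, default 2.
#' @return Lambda (scalar).
#' @export
genomic_lambda <- function(wald_statistics, digits = 2) {
  x <- wald_statistics[is.finite(wald_statistics)]
  if (!length(x)) stop("no statistics supplied")
  if (length(x) < 100)
    warning("fewer than 100 statistics; lambda is unstable")
  round(stats::median(x) / stats::qchisq(0.5, 1), digits)
}

#' Classify association hits
#'
#' Labels each SNP `genomewide` (p < `genomewide`), `suggestive`
#' (`genomewide` <= p < `suggestive`) or `none`.
#'
#' @param assoc Association data frame with a `p` column.
#' @param genomewide,suggestive Thresholds, defaults 5e-8 and 1e-5.
#' @return The data frame with an added `label` column.
#' @export
classify_hits <- function(assoc, genomewide = 5e-8, suggestive = 1e-5) {
  stopifnot(all(assoc$p > 0 & assoc$p <= 1))
  lab <- rep("none", nrow(assoc))
  lab[assoc$p < suggestive] <- "suggestive"
  lab[assoc$p < genomewide] <- "genomewide"
  assoc$label <- lab
  assoc
}

#' Observed-vs-expected table for a Q-Q plot
#'
#' @param p P-values.
#' @return Data frame with `expected` and `observed` -log10 p, sorted.
#' @export
qq_table <- function(p) {
  p <- sort(p[is.finite(p)])
  m <- length(p)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(p))
}
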