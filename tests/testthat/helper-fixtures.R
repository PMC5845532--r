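# shared fixture builders for the suite

# tiny hand-written cohort: 5 MZf pairs with clean labs
toy_cohort <- function() {
  n <- 5
  data.frame(
    pair_id = rep(1:n, each = 2),
    group = "MZf", twin = rep(1:2, n), sex = "F",
    age = rep(c(45, 50, 55, 60, 65), each = 2),
    bmi = 24, sua = c(200, 210, 250, 240, 300, 310, 180, 190, 260, 255),
    gout = FALSE, sle = FALSE, egfr = 90, creatinine = 0.9,
    stringsAsFactors = FALSE)
}

# cohort with no covariate effects and unit latent scale, for moment checks
plain_covariates <- function(sd = 1)
  covariate_spec(intercept_f = 0, intercept_m = 0, beta_age = 0,
                 beta_bmi = 0, beta_age_sex = 0, sd = sd)

# within-pair sample covariance / correlation of one group
pair_cov <- function(cohort, grp, what = c("cov", "cor")) {
  what <- match.arg(what)
  co <- cohort[cohort$group == grp, ]
  y1 <- co$sua[co$twin == 1][order(co$pair_id[co$twin == 1])]
  y2 <- co$sua[co$twin == 2][order(co$pair_id[co$twin == 2])]
  if (what == "cov") cov(y1, y2) else cor(y1, y2)
}

# independent closed-form -2 log bivariate-normal density (oracle)
neg2ll_oracle <- function(Y, mu, Sigma) {
  sum(apply(Y, 1, function(y) {
    r <- y - mu
    log(det(Sigma)) + 2 * log(2 * pi) +
      drop(t(r) %*% solve(Sigma) %*% r)
  }))
}

# direct factorial-formula HWE enumeration (oracle, independent of the
# recurrence-free log-gamma implementation in the package)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  pr <- vapply(hets, function(h) {
    naa2 <- (na - h) / 2
    nAA2 <- (nA - h) / 2
    exp(lfactorial(n) - lfactorial(nAA2) - lfactorial(h) -
          lfactorial(naa2) + h * log(2) +
          lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= obs + 1e-12]))
}
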