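test_that("group size and parameter validation rejects bad input", {
  expect_error(group_sizes(n_mz_m = -1), "non-negative")
  expect_error(sexlim_parameters(0.5, 0.5, 0, 0.5, 0.5, 0.5), "positive")
  expect_error(sexlim_parameters(-0.1, 0.5, 0.5, 0.5, 0.5, 0.5), ">= 0")
  expect_equal(sum(unlist(group_sizes())), 379)
})

test_that("E-only MZ pairs are uncorrelated within pair", {
  par <- sexlim_parameters(0, 0, 1, 0, 0, 1)
  co <- simulate_twin_cohort(par, group_sizes(0, 1e4, 0, 0, 0),
                             plain_covariates(), seed = 42)
  expect_lt(abs(pair_cov(co, "MZf", "cor")), 0.03)
})

test_that("MZ-female correlation matches the model-implied a^2 + c^2", {
  # analytic oracle: with unit variance, r_MZ = a_f^2 + c_f^2 = 0.726
  par <- sexlim_parameters(sqrt(0.463), sqrt(0.263), sqrt(0.275 - 0.001),
                           0.5, 0.5, 0.5)
  expected <- 0.463 + 0.263
  co <- simulate_twin_cohort(par, group_sizes(0, 1e5, 0, 0, 0),
                             plain_covariates(), seed = 43)
  expect_equal(pair_cov(co, "MZf", "cor"), expected, tolerance = 0.015)
})

test_that("opposite-sex covariance is 0.5 a_f a_m + c_f c_m, Am' excluded", {
  # hand-computed: 0.5*0.6*0.5 + 0.3*0.2 = 0.21
  par <- sexlim_parameters(0.6, 0.3, 0.5, 0.5, 0.2, 0.5, am_prime = 0.4)
  co <- simulate_twin_cohort(par, group_sizes(0, 0, 0, 0, 1e5),
                             plain_covariates(), seed = 44)
  expect_equal(pair_cov(co, "DZos", "cov"), 0.21, tolerance = 0.012)
  # Am'^2 still contributes to the male (twin 2) variance
  os <- co[co$group == "DZos", ]
  v_m <- var(os$sua[os$twin == 2])
  expect_equal(v_m, 0.5^2 + 0.4^2 + 0.2^2 + 0.5^2, tolerance = 0.02)
})

test_that("group variances match the model-implied sum of squared paths", {
  par <- sexlim_parameters(0.6, 0.4, 0.5, 0.5, 0.3, 0.6, am_prime = 0.3)
  co <- simulate_twin_cohort(par, group_sizes(4000, 4000, 4000, 4000, 4000),
                             plain_covariates(), seed = 45)
  v_f <- 0.6^2 + 0.4^2 + 0.5^2
  v_m <- 0.5^2 + 0.3^2 + 0.6^2 + 0.3^2
  for (g in c("MZf", "DZf")) {
    x <- co$sua[co$group == g]
    expect_equal(var(x), v_f, tolerance = 3 * v_f * sqrt(2 / 4000))
  }
  for (g in c("MZm", "DZm")) {
    x <- co$sua[co$group == g]
    expect_equal(var(x), v_m, tolerance = 3 * v_m * sqrt(2 / 4000))
  }
  # MZ correlation exceeds DZ correlation when a^2 > 0
  expect_gt(pair_cov(co, "MZf", "cor"), pair_cov(co, "DZf", "cor"))
  expect_gt(pair_cov(co, "MZm", "cor"), pair_cov(co, "DZm", "cor"))
})

test_that("the cohort generator is reproducible and structurally valid", {
  par <- sexlim_from_shares(c(46.3, 26.3, 27.5), c(29.9, 33.1, 37.0))
  a <- simulate_twin_cohort(par, group_sizes(), covariate_spec(), seed = 7)
  b <- simulate_twin_cohort(par, group_sizes(), covariate_spec(), seed = 7)
  expect_identical(a, b)
  expect_silent(validate_cohort(a))
  expect_equal(nrow(a), 2 * 379)
  # DZos pairs are female-first
  os1 <- a[a$group == "DZos" & a$twin == 1, ]
  expect_true(all(os1$sex == "F"))
  # age is shared within pair
  expect_true(all(tapply(a$age, a$pair_id, function(x) x[1] == x[2])))
})

test_that("DZ genotypes have valid domain, IBD 1/4-1/2-1/4 and MAF", {
  sim <- simulate_dz_genotypes(2000, 500, 0.05, 0.5, seed = 5)
  g <- sim$genotypes
  expect_true(all(g[!is.na(g)] %in% 0:2))
  expect_equal(nrow(sim$meta), ncol(g))
  ibd <- attr(g, "ibd")
  # oracle: E[IBD]/2 = 0.5 under the 1/4-1/2-1/4 sibling distribution
  expect_equal(mean(ibd) / 2, 0.5, tolerance = 0.02)
  expect_equal(mean(ibd == 1), 0.5, tolerance = 0.02)
  # positions strictly increasing within chromosome
  for (ch in unique(sim$meta$chrom)) {
    pos <- sim$meta$pos[sim$meta$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
})

test_that("fixed-MAF genotypes reproduce the generating allele frequency", {
  sim <- simulate_dz_genotypes(5000, 20, 0.3, 0.3, seed = 6)
  af <- colMeans(sim$genotypes, na.rm = TRUE) / 2
  # binomial oracle: SE of a pooled frequency at 2N=20000 is ~0.003
  expect_equal(mean(af), 0.3, tolerance = 0.01)
  expect_true(all(abs(af - 0.3) < 0.03))
})

test_that("missingness is injected at the requested rate", {
  sim <- simulate_dz_genotypes(500, 200, 0.1, 0.4, missing_rate = 0.1,
                               seed = 8)
  expect_equal(mean(is.na(sim$genotypes)), 0.1, tolerance = 0.01)
  expect_error(simulate_dz_genotypes(10, 10, 0.6, 0.7), "maf")
  expect_error(simulate_dz_genotypes(10, 10, 0.1, 0.4, missing_rate = 1),
               "missing_rate")
})

test_that("spike_snp_effect adds beta times the allele count and nothing else", {
  par <- sexlim_parameters(0.5, 0.4, 0.6, 0.5, 0.4, 0.6)
  co <- simulate_twin_cohort(par, group_sizes(0, 0, 20, 20, 0),
                             plain_covariates(), seed = 9)
  dz_ids <- unique(co$pair_id)
  sim <- simulate_dz_genotypes(length(dz_ids), 10, 0.2, 0.4,
                               pair_ids = dz_ids, seed = 10)
  expect_identical(spike_snp_effect(co, sim$genotypes, 3, 0), co)
  sp <- spike_snp_effect(co, sim$genotypes, 3, 1.5)
  ids <- paste(co$pair_id, co$twin, sep = "_")
  g <- sim$genotypes[match(ids, rownames(sim$genotypes)), 3]
  expect_equal(sp$sua - co$sua, unname(1.5 * ifelse(is.na(g), 0, g)))
  expect_identical(sp[setdiff(names(sp), "sua")],
                   co[setdiff(names(co), "sua")])
  bad <- sim$genotypes
  rownames(bad)[1] <- "999_1"
  expect_error(spike_snp_effect(co, bad, 1, 1), "not in cohort")
})
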