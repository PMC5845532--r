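test_that("model specs carry the published free-path counts", {
  counts <- sapply(c("I", "II", "III", "IV", "V", "VI"),
                   function(m) model_spec(m)$n_paths)
  expect_equal(unname(counts), c(7, 6, 5, 4, 2, 3))
  expect_error(model_spec("II", scalar = TRUE), "scalar")
})

test_that("expected moments reproduce the group covariance algebra", {
  pe <- sexlim_parameters(0, 0, 1, 0, 0, 1)
  for (g in c("MZm", "MZf", "DZm", "DZf", "DZos"))
    expect_equal(expected_moments(pe, g)$cov, diag(2))
  expect_error(expected_moments(pe, "XX"), "unknown group")

  # sum oracle: MZf covariance = a_f^2 + c_f^2 = 0.463 + 0.263
  p2 <- sexlim_parameters(sqrt(0.463), sqrt(0.263), sqrt(0.274),
                          0.5, 0.5, 0.5)
  expect_equal(expected_moments(p2, "MZf")$cov[1, 2], 0.726,
               tolerance = 1e-12)

  # hand arithmetic: DZos off-diagonal and the am'^2 male variance term
  p3 <- sexlim_parameters(0.6, 0.3, 0.5, 0.5, 0.2, 0.5, am_prime = 0.4)
  mo <- expected_moments(p3, "DZos")
  expect_equal(mo$cov[1, 2], 0.21)
  expect_equal(mo$cov[2, 2], 0.25 + 0.16 + 0.04 + 0.25)
  expect_equal(expected_moments(p3, "DZm")$cov[1, 2],
               0.5 * 0.25 + 0.5 * 0.16 + 0.04)

  # means from per-twin covariates
  mo2 <- expected_moments(p3, "MZf", beta = c(2, 0.5),
                          x1 = c(1, 10), x2 = c(1, 20))
  expect_equal(mo2$mean, c(7, 12))
})

test_that("FIML -2LL equals the closed-form bivariate normal density", {
  pe <- sexlim_parameters(0, 0, 1, 0, 0, 1)
  one <- data.frame(pair_id = c(1, 1), group = "MZf", twin = 1:2,
                    sex = "F", age = 50, bmi = 24.5, sua = c(0, 0))
  expect_equal(neg2_loglik(pe, one), 2 * log(2 * pi), tolerance = 1e-10)
  one$sua <- c(1, -1)
  expect_equal(neg2_loglik(pe, one), 2 * log(2 * pi) + 2,
               tolerance = 1e-10)
  # duplicating every pair doubles the deviance
  two <- rbind(one, transform(one, pair_id = 2))
  expect_equal(neg2_loglik(pe, two), 2 * neg2_loglik(pe, one))
})

test_that("FIML matches an independent density oracle on random cohorts", {
  set.seed(11)
  par <- sexlim_parameters(0.7, 0.45, 0.55, 0.6, 0.35, 0.65,
                           am_prime = 0.25)
  co <- simulate_twin_cohort(par, group_sizes(8, 9, 7, 6, 10),
                             plain_covariates(), seed = 12)
  got <- neg2_loglik(par, co)
  pr <- split(seq_len(nrow(co)), co$pair_id)
  oracle <- 0
  for (ix in pr) {
    g <- as.character(co$group[ix[1]])
    Y <- matrix(co$sua[ix][order(co$twin[ix])], 1)
    oracle <- oracle +
      neg2ll_oracle(Y, c(0, 0), expected_moments(par, g)$cov)
  }
  expect_equal(got, oracle, tolerance = 1e-8)
  # non-PD covariance is refused
  bad <- sexlim_parameters(1, 0, 1e-9, 1, 0, 1e-9)
  expect_error(neg2_loglik(bad, co), "positive definite")
})

test_that("null-heritability cohorts are fitted as essentially all E", {
  par <- sexlim_parameters(0, 0, 1, 0, 0, 1)
  co <- simulate_twin_cohort(par, group_sizes(400, 400, 400, 400, 400),
                             plain_covariates(), seed = 13)
  f <- fit_model("II", co, means_design = means_design_intercepts,
                 n_restarts = 5, seed = 1)
  expect_gte(f$shares["female", "E"], 95)
  expect_gte(f$shares["male", "E"], 95)
})

test_that("Model II recovers the generating standardized components", {
  par <- sexlim_from_shares(c(46.3, 26.3, 27.5), c(29.9, 33.1, 37.0))
  co <- simulate_twin_cohort(par, group_sizes(1500, 1500, 1500, 1500, 1500),
                             covariate_spec(), seed = 14)
  co$sua <- blom_transform(co$sua)
  f <- fit_model("II", co, seed = 2)
  # simulation truth within ~3 Monte-Carlo SEs at 1500 pairs/group
  expect_lt(abs(f$shares["female", "A"] - 46.3), 6)
  expect_lt(abs(f$shares["female", "C"] - 26.3), 6)
  expect_lt(abs(f$shares["male", "E"] - 37.0), 5)
  expect_equal(sum(f$shares["female", ]), 100, tolerance = 0.01)
  expect_equal(sum(f$shares["male", ]), 100, tolerance = 0.01)
  # a BMI effect was simulated, so its means-model coefficient is nonzero
  expect_gt(f$beta[["bmi_c"]], 0)
})

test_that("likelihood nesting holds along the model ladder", {
  par <- sexlim_from_shares(c(40, 25, 35), c(35, 25, 40))
  co <- simulate_twin_cohort(par, group_sizes(300, 300, 300, 300, 300),
                             plain_covariates(), seed = 15)
  fits <- lapply(c("I", "II", "III", "IV", "V", "VI"), function(m)
    fit_model(m, co, means_design = means_design_intercepts,
              n_restarts = 6, seed = 3))
  names(fits) <- c("I", "II", "III", "IV", "V", "VI")
  n2 <- sapply(fits, `[[`, "neg2ll")
  tol <- 1e-4
  expect_lte(n2["I"], n2["II"] + tol)
  expect_lte(n2["II"], n2["III"] + tol)
  expect_lte(n2["III"], n2["IV"] + tol)
  expect_lte(n2["I"], n2["VI"] + tol)
  expect_lte(n2["VI"], n2["V"] + tol)
})

test_that("the fit is invariant to twin relabeling within MZ pairs", {
  par <- sexlim_from_shares(c(50, 20, 30), c(40, 20, 40))
  co <- simulate_twin_cohort(par, group_sizes(150, 150, 80, 80, 80),
                             plain_covariates(), seed = 16)
  sw <- co
  mz <- sw$group %in% c("MZm", "MZf")
  sw$twin[mz] <- 3L - sw$twin[mz]
  f1 <- fit_model("II", co, means_design = means_design_intercepts,
                  n_restarts = 4, seed = 4)
  f2 <- fit_model("II", sw, means_design = means_design_intercepts,
                  n_restarts = 4, seed = 4)
  expect_equal(f1$neg2ll, f2$neg2ll, tolerance = 1e-6)
})

test_that("df bookkeeping reproduces the published table at 379 pairs", {
  par <- sexlim_from_shares(c(46.3, 26.3, 27.5), c(29.9, 33.1, 37.0))
  co <- simulate_twin_cohort(par, group_sizes(), covariate_spec(),
                             seed = 17)
  co$sua <- blom_transform(co$sua)
  dfs <- sapply(c("I", "II", "III", "IV", "V", "VI"), function(m)
    fit_model(m, co, n_restarts = 3, seed = 5)$df)
  free <- sapply(c("I", "II", "III", "IV", "V", "VI"), function(m)
    model_spec(m)$n_paths + 5)
  expect_equal(unname(free), c(12, 11, 10, 9, 7, 8))
  expect_equal(unname(dfs), c(746, 747, 748, 749, 751, 750))
})

test_that("standardized components behave as shares", {
  pe <- sexlim_parameters(0, 0, 1, 0, 0, 1)
  expect_equal(unname(standardize_components(pe)["female", ]),
               c(0, 0, 100))
  peq <- sexlim_parameters(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  expect_equal(unname(standardize_components(peq)["male", ]),
               rep(100 / 3, 3), tolerance = 1e-10)
  pam <- sexlim_parameters(0.5, 0.4, 0.6, 0.5, 0.4, 0.6, am_prime = 0.3)
  sh <- standardize_components(pam)
  expect_equal(unname(rowSums(sh)), c(100, 100), tolerance = 0.01)
  un <- standardize_components(pam, fold_am_prime = FALSE)
  expect_equal(sh["male", "A"], un["male", "A"] + un["male", "Am"])
})

test_that("profile CIs clip at boundaries and widen with level", {
  # generating model has no A: the A estimate sits at/near 0 and the
  # lower CI bound is the clipped boundary
  par <- sexlim_parameters(0, 0.7, 0.71, 0, 0.7, 0.71)
  co <- simulate_twin_cohort(par, group_sizes(200, 200, 100, 100, 100),
                             plain_covariates(), seed = 18)
  f <- fit_model("VI", co, means_design = means_design_intercepts,
                 n_restarts = 5, seed = 6)
  ci95 <- profile_ci(f, "A")
  expect_equal(ci95[1], 0, tolerance = 1)
  expect_true(ci95[2] > ci95[1])
  ci99 <- profile_ci(f, "A", level = 0.99)
  expect_lte(ci99[1], ci95[1] + 0.5)
  expect_gte(ci99[2], ci95[2] - 0.5)
  expect_error(profile_ci(f, "nonsense"), "component")
})

test_that("profile CIs cover the generating share at roughly the level", {
  par <- sexlim_parameters(sqrt(0.5), sqrt(0.2), sqrt(0.3),
                          sqrt(0.5), sqrt(0.2), sqrt(0.3))
  hits <- 0; n_rep <- 20
  for (i in seq_len(n_rep)) {
    co <- simulate_twin_cohort(par, group_sizes(120, 120, 60, 60, 60),
                               plain_covariates(), seed = 100 + i)
    f <- fit_model("VI", co, means_design = means_design_intercepts,
                   n_restarts = 3, seed = 7)
    ci <- profile_ci(f, "A")
    if (ci[1] <= 50 && 50 <= ci[2]) hits <- hits + 1
  }
  # 95% nominal; with 20 replicates the 0.1% binomial floor is 13
  expect_gte(hits, 14)
})
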