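test_that("HWE exact test matches hand-enumerated small tables", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)        # monomorphic
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)     # enumeration over {0,2}
  expect_equal(hwe_exact_test(0, 2, 0), 1)         # observed most probable
})

test_that("HWE exact test agrees with the enumeration oracle, n <= 20", {
  for (n in 1:20) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hwe_exact_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                   tolerance = 1e-10,
                   label = sprintf("table (%d,%d,%d)", nAA, nAa, naa))
    }
  }
})

test_that("SNP QC applies the four published filters", {
  set.seed(21)
  n <- 100
  g <- matrix(rbinom(n * 4, 2, 0.25), n, 4)
  g[1:3, 1] <- NA                       # call rate 0.97 < 0.98 -> out
  g[, 3] <- rbinom(n, 2, 0.04)          # MAF ~0.04 < 0.05 -> out
  g[, 4] <- rep(c(0, 2), n / 2)         # no hets: HWE blows up -> out
  qc <- snp_qc(g, thresholds = qc_thresholds())
  expect_false(qc$keep[1])
  expect_match(qc$report$reason[1], "call_rate")
  expect_true(qc$keep[2])
  expect_false(qc$keep[3])
  expect_match(qc$report$reason[3], "maf")
  expect_false(qc$keep[4])
  expect_match(qc$report$reason[4], "hwe")
  # filter order independence: joint mask equals sequential application
  seq_keep <- with(qc$report,
    call_rate >= 0.98 & missing <= 0.05 & hwe_p >= 1e-4 & maf >= 0.05)
  expect_equal(qc$keep, seq_keep)
  expect_error(snp_qc(matrix(numeric(0), 0, 0)), "empty")
})

test_that("MAF is computed after minor-allele orientation", {
  g <- matrix(rbinom(200, 2, 0.9), 100, 2)   # stored as major counts
  qc <- snp_qc(g)
  expect_true(all(qc$report$maf <= 0.5))
  expect_true(all(qc$report$maf >= 0.05))
})

test_that("GRM has the duplication, symmetry and scaling properties", {
  set.seed(22)
  g <- matrix(rbinom(50 * 200, 2, runif(200, 0.1, 0.5)[rep(1:200, each = 50)]),
              50, 200)
  g <- rbind(g, g[1, ])                 # duplicate individual
  G <- compute_grm(g)
  expect_equal(G, t(G))
  expect_equal(G[1, 51], G[1, 1], tolerance = 1e-10)
  expect_equal(mean(diag(G)[-51]), 1, tolerance = 0.05)
  expect_error(compute_grm(cbind(g, 0)), "zero-variance")
})

test_that("sibling pairs show ~0.5 relatedness in the GRM", {
  sim <- simulate_dz_genotypes(500, 3000, 0.05, 0.5, seed = 23)
  G <- compute_grm(sim$genotypes)
  within <- G[cbind(seq(1, 999, 2), seq(2, 1000, 2))]
  expect_equal(mean(within), 0.5, tolerance = 0.03)
})

test_that("principal components separate synthetic populations", {
  set.seed(24)
  m <- 400
  p1 <- runif(m, 0.1, 0.5); p2 <- pmin(p1 + runif(m, 0.1, 0.3), 0.95)
  g <- rbind(matrix(rbinom(30 * m, 2, rep(p1, each = 30)), 30, m),
             matrix(rbinom(30 * m, 2, rep(p2, each = 30)), 30, m))
  G <- compute_grm(g)
  pcs <- genotype_pcs(G, 5)
  pc1 <- pcs[, 1]
  expect_true(abs(mean(pc1[1:30] > median(pc1)) -
                  mean(pc1[31:60] > median(pc1))) > 0.9)
  expect_equal(crossprod(pcs), diag(5), tolerance = 1e-8)
  expect_equal(ncol(genotype_pcs(G, 0)), 0)
  expect_error(genotype_pcs(G, 100), "rank")
})

test_that("LMM collapses to OLS with identity GRM and null heritability", {
  set.seed(25)
  n <- 120; m <- 30
  g <- matrix(rbinom(n * m, 2, 0.3), n, m)
  age <- runif(n, 40, 70)
  y <- 1 + 0.1 * age + rnorm(n)
  # with an identity GRM the weights are uniform for every variance
  # ratio, so the scan is exactly OLS whatever the profile returns
  res <- lmm_assoc(g, y, cbind(age = age), diag(n))
  for (j in c(1, 7, 30)) {
    ols <- summary(lm(y ~ age + g[, j]))$coefficients
    # orientation may flip the sign of beta, never the test
    expect_equal(abs(res$assoc$beta[j]), abs(ols[3, 1]), tolerance = 1e-8)
    expect_equal(res$assoc$se[j], ols[3, 2], tolerance = 1e-8)
    expect_equal(res$assoc$p[j],
                 pchisq((ols[3, 1] / ols[3, 2])^2, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("LMM beta matches the normal-equations slope on a toy set", {
  y <- c(1.2, 0.5, -0.3, 2.0, 1.1, 0.4)
  x <- c(0, 1, 0, 2, 1, 0)
  res <- lmm_assoc(matrix(x, 6, 1), y, matrix(1, 6, 1), diag(6))
  xc <- x - mean(x); yc <- y - mean(y)
  expect_equal(res$assoc$beta, sum(xc * yc) / sum(xc^2), tolerance = 1e-10)
})

test_that("a spiked SNP dominates the association scan", {
  par <- sexlim_parameters(0.4, 0.4, 0.82, 0.4, 0.4, 0.82)
  co <- simulate_twin_cohort(par, group_sizes(0, 0, 500, 500, 0),
                             plain_covariates(), seed = 26)
  ids <- unique(co$pair_id)
  sim <- simulate_dz_genotypes(1000, 150, 0.3, 0.3, pair_ids = ids,
                               seed = 27)
  co <- spike_snp_effect(co, sim$genotypes, 42, 0.5)
  co <- co[order(co$pair_id, co$twin), ]
  ids_ind <- paste(co$pair_id, co$twin, sep = "_")
  g <- sim$genotypes[match(ids_ind, rownames(sim$genotypes)), ]
  G <- compute_grm(g)
  male <- as.numeric(co$sex == "M")
  res <- lmm_assoc(g, co$sua, cbind(sex = male), G)
  expect_equal(which.min(res$assoc$p), 42)
  expect_lt(res$assoc$p[42], 1e-5)
})

test_that("genomic lambda is definitional and scale-equivariant", {
  expect_equal(genomic_lambda(rep(qchisq(0.5, 1), 200)), 1)
  set.seed(28)
  w <- rchisq(5000, 1)
  expect_equal(genomic_lambda(2 * w, digits = 6),
               round(2 * median(w) / qchisq(0.5, 1), 6))
  expect_warning(genomic_lambda(rchisq(50, 1)), "unstable")
  expect_error(genomic_lambda(numeric(0)), "no statistics")
})

test_that("hit classification uses the published thresholds", {
  assoc <- data.frame(snp = letters[1:4],
                      p = c(2.5e-7, 1, 4e-8, 9.99e-6))
  lab <- classify_hits(assoc)$label
  expect_equal(lab, c("suggestive", "none", "genomewide", "suggestive"))
  expect_equal(classify_hits(data.frame(p = 1e-5))$label, "none")
})

test_that("qq tables are sorted and sized for plotting", {
  set.seed(29)
  q <- qq_table(runif(1000))
  expect_equal(nrow(q), 1000)
  expect_true(all(diff(q$observed) <= 0))
  expect_true(all(diff(q$expected) <= 0))
})
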