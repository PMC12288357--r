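test_that("twin-pair simulation is deterministic under a fixed seed", {
  p <- scenario_paths("genetically_driven")
  s1 <- simulate_twin_pairs(p, 50, 20, seed = 123)
  s2 <- simulate_twin_pairs(p, 50, 20, seed = 123)
  expect_identical(s1, s2)
  s3 <- simulate_twin_pairs(p, 50, 20, seed = 124)
  expect_false(identical(s1$mz, s3$mz))
})

test_that("no cross-trait path means independent variables", {
  p <- scenario_paths("null")
  s <- simulate_twin_pairs(p, 5000, 1, seed = 5)
  expect_lt(abs(cor(s$mz[, "x1"], s$mz[, "y1"])), 0.05)
})

test_that("empirical covariance converges to the model-implied matrix", {
  # the simulator goes through latent components, the target through path
  # algebra; agreement is a two-route check (3 MC standard errors at n=5e4)
  set.seed(88)
  for (p in list(scenario_paths("genetically_driven"),
                 path_coefficients("ADE", a = c(0.5, 0.2, 0.4),
                                   d = c(0.5, 0.1, 0.3),
                                   e = c(0.5, -0.1, 0.6)))) {
    n <- 50000
    s <- simulate_twin_pairs(p, n, n, seed = 42)
    for (z in c("mz", "dz")) {
      emp <- crossprod(scale(s[[z]], scale = FALSE)) / (n - 1)
      expected <- expected_twin_covariance(p, toupper(z))
      # MC standard error of a covariance entry, approximated elementwise
      mc_se <- sqrt((outer(diag(expected), diag(expected)) + expected^2) / n)
      expect_true(all(abs(emp - expected) < 3.5 * mc_se),
                  label = paste("covariance match", p$model, z))
    }
  }
})

test_that("single-trait cross-twin covariances hit A and D weights", {
  p <- path_coefficients("ACE", a = c(1, 0, 1), e = c(1, 0, 1))
  s <- simulate_twin_pairs(p, 20000, 20000, seed = 9)
  expect_equal(cov(s$mz[, "x1"], s$mz[, "x2"]), 1.0, tolerance = 0.05)
  expect_equal(cov(s$dz[, "x1"], s$dz[, "x2"]), 0.5, tolerance = 0.05)
})

test_that("MZ resemblance is at least DZ resemblance when heritable", {
  p <- scenario_paths("genetically_driven")
  s <- simulate_twin_pairs(p, 20000, 20000, seed = 10)
  expect_gt(cor(s$mz[, "x1"], s$mz[, "x2"]),
            cor(s$dz[, "x1"], s$dz[, "x2"]))
})

test_that("cohort simulation emits a consistent, reproducible cohort", {
  cfg <- simulation_config(n_mz_pairs = 378L, n_dz_pairs = 159L,
                           n_cpgs = 10L, seed = 3L)
  co <- simulate_cohort(cfg)
  expect_s3_class(co, "twin_cohort")
  expect_equal(dim(co$beta), c(10L, 2L * (378L + 159L)))
  expect_true(all(co$beta > 0 & co$beta < 1))
  expect_equal(sum(co$pheno$zygosity == "MZ"), 756L)
  expect_equal(nrow(co$truth), 10L)
  # twins share age and pair id; MZ co-twins share sex
  byp <- split(co$pheno, co$pheno$pair_id)
  expect_true(all(vapply(byp, function(d) d$age[1] == d$age[2], TRUE)))
  mzp <- byp[vapply(byp, function(d) d$zygosity[1] == "MZ", TRUE)]
  expect_true(all(vapply(mzp, function(d) d$sex[1] == d$sex[2], TRUE)))
  # anthropometric identities hold as generated
  expect_equal(co$pheno$bmi, co$pheno$weight / co$pheno$height^2,
               tolerance = 1e-2)
  expect_equal(co$pheno$whr, co$pheno$wc / co$pheno$hc, tolerance = 1e-2)
  # determinism
  co2 <- simulate_cohort(cfg)
  expect_identical(co$beta, co2$beta)
  expect_identical(co$pheno, co2$pheno)
})

test_that("zero age/sex effects leave no covariate signal", {
  cfg <- simulation_config(n_mz_pairs = 300L, n_dz_pairs = 120L,
                           n_cpgs = 2L, age_effect = 0, sex_effect = 0,
                           seed = 12L)
  co <- simulate_cohort(cfg)
  fit <- lm(co$pheno$bmi ~ co$pheno$age + factor(co$pheno$sex))
  expect_true(all(summary(fit)$coefficients[-1, "Pr(>|t|)"] > 0.01))
})

test_that("inverse-logit link keeps beta strictly inside (0, 1)", {
  cfg <- simulation_config(n_mz_pairs = 50L, n_dz_pairs = 20L, n_cpgs = 3L,
                           beta_link = "inverse-logit", baseline_beta = 0.9,
                           beta_scale = 0.3, seed = 4L)
  co <- simulate_cohort(cfg)
  expect_true(all(co$beta > 0 & co$beta < 1))
})

test_that("SNP layer: MZ identity, HWE mean, and inert empty effects", {
  co <- small_cohort()
  co_snp <- simulate_snp_layer(co, n_snps = 80L, maf_range = c(0.5, 0.5),
                               n_meqtl = 10L, seed = 21L)
  G <- co_snp$genotypes
  expect_true(all(G %in% 0:2))
  # MZ co-twins genotype-identical at every SNP
  byp <- split(seq_len(nrow(co$pheno)), co$pheno$pair_id)
  for (ii in byp[1:20]) {
    if (co$pheno$zygosity[ii[1]] == "MZ")
      expect_identical(unname(G[, ii[1]]), unname(G[, ii[2]]))
  }
  # HWE at maf = 0.5: mean genotype 1, genotype frequencies 1/4,1/2,1/4
  expect_equal(mean(G), 1, tolerance = 0.05)
  expect_equal(mean(G == 1), 0.5, tolerance = 0.05)
  # empty effect map leaves methylation and trait untouched
  expect_identical(co_snp$beta, co$beta)
  expect_identical(co_snp$pheno$bmi, co$pheno$bmi)
  expect_error(simulate_snp_layer(co, maf_range = c(0, 0.6)), "maf_range")
})

test_that("SNP effects create the shared-genetic-basis structure", {
  co <- small_cohort()
  eff <- data.frame(cpg = rownames(co$beta)[1], beta_cpg = 0.05,
                    beta_trait = 2)
  co_snp <- simulate_snp_layer(co, n_snps = 30L, meqtl_effects = eff,
                               n_meqtl = 5L, seed = 31L)
  expect_true(co_snp$meqtl$cpg[1] == rownames(co$beta)[1])
  expect_true(co_snp$meqtl$snp[1] %in% co_snp$gwas)
  g <- co_snp$genotypes[co_snp$meqtl$snp[1], ]
  expect_gt(cor(g, co_snp$beta[1, ]), 0.1)
  expect_gt(cor(g, co_snp$pheno$bmi), 0.1)
})
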