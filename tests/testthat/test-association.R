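test_that("bh_adjust equals the brute-force step-up definition", {
  set.seed(52)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_equal(bh_adjust(0.03), 0.03)                 # m = 1 identity
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))   # ties unchanged
  # stable under reordering: adjusted value sticks to its index
  p <- c(0.04, 0.001, 0.2, 0.01)
  o <- sample(4)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("within-pair design does the stated arithmetic", {
  co <- small_cohort()
  d <- make_within_pair_design(co, "bmi")
  # two rows per complete MZ pair, none for DZ
  expect_equal(nrow(d), 2L * 100L)
  expect_true(all(d$pair_id %in% co$pheno$pair_id[co$pheno$zygosity == "MZ"]))
  # antisymmetric differences, shared means
  byp <- split(d, d$pair_id)
  expect_true(all(vapply(byp, function(x) x$x_diff[1] == -x$x_diff[2], TRUE)))
  expect_true(all(vapply(byp, function(x) x$x_mean[1] == x$x_mean[2], TRUE)))
  # worked example: traits (26, 24) -> diffs (+2, -2), means (25, 25)
  co2 <- co
  pid <- d$pair_id[1]
  co2$pheno$bmi[co2$pheno$pair_id == pid] <- c(26, 24)
  d2 <- make_within_pair_design(co2, "bmi")
  expect_equal(d2$x_diff[d2$pair_id == pid], c(2, -2))
  expect_equal(d2$x_mean[d2$pair_id == pid], c(25, 25))
  # a pair with a missing twin is dropped and counted
  co3 <- co
  co3$pheno$bmi[co3$pheno$pair_id == pid][1] <- NA
  d3 <- make_within_pair_design(co3, "bmi")
  expect_equal(attr(d3, "n_dropped"), 1L)
  expect_false(pid %in% d3$pair_id)
})

test_that("cohort-proportioned design has 756 rows", {
  co <- simulate_cohort(simulation_config(n_mz_pairs = 378L,
                                          n_dz_pairs = 159L, n_cpgs = 1L,
                                          seed = 61L))
  expect_equal(nrow(make_within_pair_design(co, "bmi")), 756L)
})

test_that("full-population model detects an environmental association", {
  co <- small_cohort()
  ind <- which(co$truth$scenario == "independent")[1]
  r <- fit_full_population(co$beta[ind, ], co$pheno, "bmi")
  expect_lt(r$p, 0.01)
  expect_equal(r$n_used, nrow(co$pheno))
  expect_true(r$method %in% c("lmm", "lm_cluster"))
  expect_error(fit_full_population(co$beta[1, ], transform(co$pheno, bmi = 1),
                                   "bmi"), "constant")
})

test_that("full-population model on independent singletons matches plain OLS", {
  # one twin per pair: the pair random intercept has nothing to absorb and
  # the fixed coefficients must agree with ordinary regression
  co <- small_cohort()
  keep <- !duplicated(co$pheno$pair_id)
  ph <- co$pheno[keep, ]
  y <- co$beta[2, keep]
  r <- fit_full_population(y, ph, "bmi", min_pairs = 20L)
  ols <- lm(y ~ ph$bmi + ph$age + factor(ph$sex) +
              factor(ph$smoking, levels = c("current", "former", "never")) +
              factor(ph$drinking, levels = c("current", "former", "never")) +
              factor(ph$zygosity))
  expect_equal(r$beta, unname(coef(ols)["ph$bmi"]), tolerance = 1e-6)
})

test_that("MZ within-pair model reports the x_diff coefficient", {
  co <- small_cohort()
  d <- make_within_pair_design(co, "bmi")
  ind <- which(co$truth$scenario == "independent")[1]
  r <- fit_mz_within_pair(co$beta[ind, d$sample_id], d)
  expect_lt(r$p, 0.05) # e21-driven association survives genetic control
  # degenerate predictor is refused
  d0 <- d; d0$x_diff <- 0
  expect_error(fit_mz_within_pair(co$beta[ind, d0$sample_id], d0),
               "zero variance")
  expect_error(fit_mz_within_pair(co$beta[ind, d$sample_id][1:10], d[1:10, ],
                                  min_pairs = 20L), "fewer than")
})

test_that("assoc_scan adjusts within the design family and keeps failures", {
  co <- small_cohort()
  res <- assoc_scan(co, "bmi", "full")
  expect_equal(nrow(res), 8L)
  expect_equal(res$fdr_p, bh_adjust(res$p))
  expect_true(all(res$fdr_p >= res$p))
  res_mz <- assoc_scan(co, "bmi", "mz_paired")
  expect_equal(nrow(res_mz), 8L)
  expect_true(all(res_mz$design == "mz_paired"))
})
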