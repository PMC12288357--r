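test_that("cohort files round-trip exactly", {
  co <- small_cohort()
  co_snp <- simulate_snp_layer(co, n_snps = 40L, n_meqtl = 8L, seed = 77L)
  dir <- withr::local_tempdir()
  write_cohort(co_snp, dir)
  back <- read_cohort(dir)
  expect_equal(back$beta, co_snp$beta)
  expect_equal(back$genotypes, co_snp$genotypes)
  expect_equal(back$meqtl, co_snp$meqtl)
  expect_equal(back$gwas, co_snp$gwas)
  expect_equal(back$truth$scenario, co_snp$truth$scenario)
  expect_equal(back$truth$ra, co_snp$truth$ra, tolerance = 1e-12)
  ph <- back$pheno
  expect_equal(ph[, c("sample_id", "pair_id", "zygosity", "sex", "smoking",
                      "drinking")],
               co_snp$pheno[, c("sample_id", "pair_id", "zygosity", "sex",
                                "smoking", "drinking")])
  expect_equal(ph$bmi, co_snp$pheno$bmi, tolerance = 1e-9)
  # missing values survive the trip as NA
  co2 <- co_snp
  co2$beta[1, 3] <- NA
  co2$pheno$bmi[5] <- NA
  write_cohort(co2, dir)
  back2 <- read_cohort(dir)
  expect_true(is.na(back2$beta[1, 3]))
  expect_true(is.na(back2$pheno$bmi[5]))
})

test_that("readers reject malformed input with positional messages", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  bad <- co$beta
  bad[2, 4] <- 1.2
  f <- file.path(dir, "bad.tsv")
  expect_error(write_methylation(bad, f), "out of \\[0, 1\\]")
  # write bypassing validation, then read
  df <- data.frame(cpg_id = rownames(bad), bad, check.names = FALSE)
  writeLines("# twinmeth methylation v1", f)
  suppressWarnings(write.table(df, f, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  err <- tryCatch(read_methylation(f), error = conditionMessage)
  expect_match(err, rownames(bad)[2])
  expect_match(err, colnames(bad)[4])
  # wrong schema header
  writeLines(c("# something else", "x\ty"), f)
  expect_error(read_methylation(f), "schema")
  expect_error(read_methylation(file.path(dir, "nope.tsv")), "not found")
  # invalid categorical levels
  ph <- co$pheno
  ph$zygosity[1] <- "XX"
  pf <- file.path(dir, "ph.csv")
  write_table_with_header <- twinmeth:::write_table_with_header
  write_table_with_header(ph, pf, "phenotypes", ",")
  expect_error(read_phenotypes(pf), "zygosity")
})

test_that("average_repeated follows the two-closest rule", {
  expect_equal(average_repeated(c(100.0, 100.4)), 100.2)
  expect_equal(average_repeated(c(100.0, 101.5, 100.4)), 100.2)
  expect_equal(average_repeated(c(5, 3, 4.2)), 4.6) # closest pair (5, 4.2)
  # symmetric spacing: both candidate pairs contain the median -> median
  expect_equal(average_repeated(c(1, 2, 3)), 2)
  expect_warning(average_repeated(c(100, 103)), "third measurement")
  expect_error(average_repeated(100), "2 or 3")
  expect_error(average_repeated(c(1, NA, 3)), "finite")
})

test_that("derive_indices computes BMI and WHR and warns on unit errors", {
  ph <- data.frame(weight = 81, height = 1.8, wc = 90, hc = 100)
  out <- derive_indices(ph)
  expect_equal(out$bmi, 25.0)
  expect_equal(out$whr, 0.9)
  expect_warning(derive_indices(transform(ph, height = 180)), "unit")
  ph2 <- transform(ph, bmi = 30) # inconsistent existing value
  expect_warning(out2 <- derive_indices(ph2), "inconsistent")
  expect_equal(out2$bmi, 25.0)
})

test_that("zygosity calls follow the 90% identity rule", {
  expect_equal(call_zygosity(rep(1, 59), rep(1, 59))$call, "MZ")
  g2 <- c(rep(1, 54), rep(0, 5))
  expect_equal(call_zygosity(rep(1, 59), g2)$call, "MZ")       # 54/59 = 0.915
  g3 <- c(rep(1, 53), rep(0, 6))
  expect_equal(call_zygosity(rep(1, 59), g3)$call, "DZ")       # 53/59 = 0.898
  few <- call_zygosity(rep(1, 10), rep(1, 10))
  expect_equal(few$call, "indeterminate")
  expect_equal(few$n_snps_compared, 10)
  # missing genotypes are excluded from the comparison
  ga <- c(NA, rep(1, 40)); gb <- c(0, rep(1, 40))
  expect_equal(call_zygosity(ga, gb)$identity_fraction, 1)
  expect_error(call_zygosity(1:5, 1:4), "length")
})

test_that("panel-based calls recover simulated zygosity", {
  co <- simulate_snp_layer(small_cohort(), n_snps = 59L,
                           maf_range = c(0.2, 0.5), n_meqtl = 0L, seed = 3L)
  calls <- call_zygosity_pairs(co$genotypes, co$pheno)
  truth <- co$pheno$zygosity[match(calls$pair_id, co$pheno$pair_id)]
  expect_true(all(calls$call[truth == "MZ"] == "MZ"))
  expect_gt(mean(calls$call[truth == "DZ"] == "DZ"), 0.9)
})

test_that("annotation table reads with the documented columns", {
  f <- system.file("extdata", "annotation_synthetic.tsv",
                   package = "twinmeth")
  ann <- read_annotation(f)
  row <- ann[ann$cpg == "cg06500161", ]
  expect_equal(row$gene, "ABCG1")
  expect_equal(row$locus, "Body")
  expect_true(row$enhancer)
  expect_equal(row$chr, 21)
  # round trip
  dir <- withr::local_tempdir()
  f2 <- file.path(dir, "ann.tsv")
  write_annotation(ann, f2)
  expect_equal(read_annotation(f2), ann)
})

test_that("SNP list I/O round-trips", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "gwas.txt")
  write_snp_list(c("rs1", "rs2"), f)
  expect_equal(read_snp_list(f), c("rs1", "rs2"))
})
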