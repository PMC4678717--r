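test_that("ped/map fixture round-trips to the expected minor-allele matrix", {
  fx <- write_pedmap_fixture(withr::local_tempdir())
  g <- read_genotypes(paste0(fx$base, ".ped"), "ped_map")
  expect_s3_class(g, "genotype_dataset")
  expect_identical(g$samples, fx$samples)
  expect_identical(g$snps$snp_id, fx$snp_ids)
  expect_identical(unname(g$calls), fx$expected)
  expect_identical(g$snps$chrom, c("1", "2"))
  expect_identical(g$snps$pos, c(1000L, 2000L))
})

test_that("ped with a column count inconsistent with the map errors", {
  dir <- withr::local_tempdir()
  fx <- write_pedmap_fixture(dir)
  writeLines(c("1 rsA 0 1000", "2 rsB 0 2000", "3 rsC 0 3000"),
             paste0(fx$base, ".map"))
  expect_error(read_genotypes(paste0(fx$base, ".ped"), "ped_map"),
               "dimension error")
})

test_that("VCF ./. becomes a missing call and GT dosages are recoded", {
  skip_if_not_installed("VariantAnnotation")
  path <- write_vcf_fixture(withr::local_tempdir())
  g <- read_genotypes(path, "vcf")
  expect_identical(g$samples, c("NA1", "NA2", "NA3"))
  # rsV1: ALT G is minor (1/4 called alleles) -> 0, NA, 1
  expect_identical(unname(g$calls[, 1]), c(0L, NA_integer_, 1L))
  # rsV2: ALT T has frequency 5/6 -> flipped to REF counts 0, 1, 0
  expect_identical(unname(g$calls[, 2]), c(0L, 1L, 0L))
  expect_identical(g$snps$pos, c(100L, 200L))
})

test_that("TSV matrix reader preserves header SNP order and matches an independent parse", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.tsv")
  set.seed(11)
  calls <- matrix(sample(c(0:2, NA), 40, replace = TRUE,
                         prob = c(.45, .3, .15, .1)), 8, 5)
  ids <- c("rzZ", "rsA", "rsM", "rsB", "rsQ")  # deliberately unsorted
  writeLines(c(paste(c("sample_id", ids), collapse = "\t"),
               vapply(1:8, function(i)
                 paste(c(paste0("ind", i),
                         ifelse(is.na(calls[i, ]), "NA", calls[i, ])),
                       collapse = "\t"), character(1))),
             path)
  g <- read_genotypes(path, "tsv_matrix")
  expect_identical(g$snps$snp_id, ids)
  # independent line-by-line parse
  lines <- strsplit(readLines(path)[-1], "\t")
  manual <- t(vapply(lines, function(x)
    suppressWarnings(as.integer(x[-1])), integer(5)))
  manual <- apply(manual, 2, function(col) {
    if (mean(col, na.rm = TRUE) / 2 > 0.5) 2L - col else col
  })
  expect_identical(unname(g$calls), manual)
})

test_that("write_genotypes/read_genotypes round-trip preserves the matrix", {
  d <- null_dataset(30, 8, maf = 0.25, seed = 5)$geno
  d$calls[2, 3] <- NA_integer_
  d <- validate_genotype_dataset(d)
  path <- file.path(withr::local_tempdir(), "rt.tsv")
  write_genotypes(d, path)
  g2 <- read_genotypes(path, "tsv_matrix")
  expect_identical(unname(g2$calls), unname(d$calls))
  expect_identical(g2$samples, d$samples)
})

test_that("minor_allele_frequency handles the boundary and missing cases", {
  expect_equal(minor_allele_frequency(c(0L, 0L, 0L, 0L)), 0)
  expect_equal(minor_allele_frequency(c(1L, 1L, 1L, 1L)), 0.5)
  expect_equal(minor_allele_frequency(c(2L, 1L, 0L, NA)), 0.5)
  expect_error(minor_allele_frequency(c(NA_integer_, NA_integer_)),
               "all calls missing")
})

test_that("minor_allele_frequency is invariant to sample order", {
  withr::with_seed(3, {
    for (i in 1:20) {
      g <- sample(c(0:2, NA), 50, replace = TRUE)
      if (all(is.na(g))) next
      expect_identical(minor_allele_frequency(g),
                       minor_allele_frequency(sample(g)))
    }
  })
})

test_that("hwe_exact_pvalue matches its stated examples", {
  expect_equal(hwe_exact_pvalue(0, 0, 50), 1.0)
  expect_lt(hwe_exact_pvalue(0, 100, 0), 1e-6)
  # frozen from the enumeration oracle (hwe_oracle(25, 50, 25))
  expect_equal(hwe_exact_pvalue(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
})

test_that("hwe_exact_pvalue agrees with the enumeration oracle on random tables", {
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(1:150, 1)
      na <- sample(0:n, 1)
      hs <- seq.int(na %% 2, na, by = 2)
      h <- sample(hs, 1)
      nAA <- n - h - (na - h) / 2
      expect_equal(hwe_exact_pvalue(nAA, h, (na - h) / 2),
                   hwe_oracle(nAA, h, (na - h) / 2), tolerance = 1e-10)
    }
  })
})

test_that("HWE exact test rejects ~5% of HWE-simulated SNPs at alpha=0.05", {
  # n = 5000 diploids, MAF 0.2, 1000 replicates (spec-scale calibration)
  p <- withr::with_seed(21, vapply(1:1000, function(i) {
    g <- sample.int(3, 5000, TRUE, prob = c(0.64, 0.32, 0.04)) - 1L
    hwe_exact_pvalue(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1)))
  band <- binom_band(1000, 0.05)
  expect_gte(mean(p < 0.05), band[1])
  expect_lte(mean(p < 0.05), band[2])
})

test_that("genotype_r2 matches its examples and is symmetric", {
  x <- c(0L, 0L, 1L, 1L, 2L, 2L)
  expect_equal(genotype_r2(x, x), 1)
  expect_equal(genotype_r2(x, 2L - x), 1)
  expect_error(genotype_r2(x, rep(1L, 6)), "constant")
  big <- null_dataset(10000, 2, maf = 0.3, seed = 9)$geno
  r2 <- genotype_r2(big$calls[, 1], big$calls[, 2])
  expect_lt(r2, 0.01)  # independent SNPs
  withr::with_seed(13, {
    for (i in 1:10) {
      a <- sample(0:2, 30, TRUE); b <- sample(0:2, 30, TRUE)
      if (var(a) == 0 || var(b) == 0) next
      expect_equal(genotype_r2(a, b), genotype_r2(b, a))
    }
  })
})

test_that("pi_hat recovers the duplicate, unrelated and parent-offspring limits", {
  maf <- rep(0.3, 1000)
  po <- simulate_parent_offspring(maf, seed = 31)
  other <- withr::with_seed(32, as.integer(rbinom(1000, 2, maf)))
  expect_gt(pi_hat(po$parent, po$parent, maf), 0.9)     # duplicate
  expect_lt(pi_hat(po$parent, other, maf), 0.1)         # unrelated
  ph <- pi_hat(po$parent, po$child, maf)                # first degree
  expect_gte(ph, 0.35); expect_lte(ph, 0.65)
  expect_error(pi_hat(po$parent[1:30], po$child[1:30], maf[1:30]),
               "insufficient data")
})

test_that("apply_qc removes a low-call-rate sample at stage 1", {
  d <- null_dataset(20, 30, maf = 0.4, seed = 41)$geno
  d$calls[3, 1:9] <- NA_integer_   # 70% call rate < 90%
  d <- validate_genotype_dataset(d)
  res <- apply_qc(d, qc_thresholds(maf_min = 0, hwe_p_min = 0,
                                   pihat_min_snps = 30))
  expect_equal(res$report$samples_removed[res$report$stage ==
                                            "sample_call_rate"], 1)
  expect_false("ind00003" %in% res$dataset$samples)
})

test_that("apply_qc prunes exactly one of two duplicated SNP columns", {
  d <- null_dataset(50, 10, maf = 0.4, seed = 43)$geno
  d$calls[, 6] <- d$calls[, 5]   # r2 = 1 duplicate pair
  d <- validate_genotype_dataset(d)
  res <- apply_qc(d, qc_thresholds(maf_min = 0, hwe_p_min = 0,
                                   pihat_min_snps = 10))
  ids <- res$dataset$snps$snp_id
  expect_true(xor("snp0005" %in% ids, "snp0006" %in% ids))
  # map-order tie-break: the later SNP goes
  expect_true("snp0005" %in% ids)
})

test_that("apply_qc is a no-op on clean data and is idempotent", {
  # pi-hat needs a few hundred SNPs to separate unrelateds from the
  # 0.3 threshold; 300 keeps this stage quiet on clean data
  d <- null_dataset(30, 300, maf = 0.35, seed = 47)$geno
  th <- qc_thresholds()
  res <- apply_qc(d, th)
  expect_equal(sum(res$report$samples_removed), 0)
  expect_equal(sum(res$report$snps_removed), 0)
  expect_identical(res$dataset$calls, d$calls)
  # idempotence on data that did get filtered (MAF well away from the
  # 0.05 threshold so re-estimation after sample removal cannot cascade)
  d2 <- null_dataset(40, 300, maf = 0.2, seed = 48)$geno
  d2$calls[, 3] <- d2$calls[, 2]
  d2$calls[5, 1:150] <- NA_integer_
  d2 <- validate_genotype_dataset(d2)
  th2 <- qc_thresholds(maf_min = 0.05)
  once <- apply_qc(d2, th2)
  twice <- apply_qc(once$dataset, th2)
  expect_identical(twice$dataset$calls, once$dataset$calls)
  expect_equal(sum(twice$report$samples_removed) +
                 sum(twice$report$snps_removed), 0)
})

test_that("qc_report counts reconcile: removed + surviving = input", {
  d <- null_dataset(40, 25, maf = 0.1, seed = 51)$geno
  d$calls[2, 1:20] <- NA_integer_
  d <- validate_genotype_dataset(d)
  res <- apply_qc(d, qc_thresholds(pihat_min_snps = 20))
  r <- res$report
  expect_equal(r$samples_left[1], 40 - r$samples_removed[1])
  for (i in 2:nrow(r)) {
    expect_equal(r$samples_left[i],
                 r$samples_left[i - 1] - r$samples_removed[i])
    expect_equal(r$snps_left[i], r$snps_left[i - 1] - r$snps_removed[i])
  }
})

test_that("relatedness stage removes one member of a duplicated sample pair", {
  base <- null_dataset(30, 500, maf = 0.3, seed = 53)$geno
  base$calls[7, ] <- base$calls[12, ]   # duplicate individuals
  base$calls[7, 1:10] <- NA_integer_    # give ind 7 the lower call rate
  base <- validate_genotype_dataset(base)
  res <- apply_qc(base, qc_thresholds(maf_min = 0.01, snp_call_rate_min = 0.5))
  expect_equal(res$report$samples_removed[res$report$stage ==
                                            "relatedness"], 1)
  expect_false("ind00007" %in% res$dataset$samples)  # lower call rate goes
  expect_true("ind00012" %in% res$dataset$samples)
})
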