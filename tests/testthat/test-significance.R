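test_that("null vector length is n_perm x top_k and runs are reproducible", {
  d <- null_dataset(60, 4, maf = 0.3, seed = 1)
  plan <- make_fold_plan(60, 10, seed = 2)
  null <- build_null(d$geno, d$trait, plan,
                     candidate_snps = d$geno$snps$snp_id,
                     n_perm = 2, top_k = 3, seed = 5)
  expect_equal(length(null$statistics) + null$n_undefined, 2 * 3)
  null2 <- build_null(d$geno, d$trait, plan,
                      candidate_snps = d$geno$snps$snp_id,
                      n_perm = 2, top_k = 3, seed = 5)
  expect_identical(null$statistics, null2$statistics)
  null3 <- build_null(d$geno, d$trait, plan,
                      candidate_snps = d$geno$snps$snp_id,
                      n_perm = 2, top_k = 3, seed = 6)
  expect_false(identical(null$statistics, null3$statistics))
})

test_that("unselected null pool is centred near zero under no signal", {
  # top_k = all 45 pairs: no selection, the pooled testing statistics
  # are symmetric about 0 (a top-k-selected pool is upward-shifted by
  # construction and is not tested against 0)
  d <- null_dataset(300, 10, maf = 0.3, seed = 99)
  plan <- make_fold_plan(300, 10, seed = 5)
  null <- build_null(d$geno, d$trait, plan,
                     candidate_snps = d$geno$snps$snp_id,
                     n_perm = 200, top_k = 45, seed = 11)
  expect_lt(abs(mean(null$statistics)), 0.1)
})

test_that("empirical_pvalue follows the add-one rule", {
  null <- structure(list(statistics = as.numeric(1:99), n_perm = 99L,
                         top_k = 1L, seed = 1L, n_undefined = 0L),
                    class = "null_distribution")
  expect_equal(as.numeric(empirical_pvalue(100, null)), 0.01)
  expect_equal(attr(empirical_pvalue(100, null), "raw"), 0)
  null999 <- structure(list(statistics = as.numeric(1:999)),
                       class = "null_distribution")
  expect_equal(as.numeric(empirical_pvalue(500, null999)), 0.501,
               tolerance = 0.01)
  expect_equal(as.numeric(empirical_pvalue(-Inf, null)), 1.0)
  expect_equal(as.numeric(empirical_pvalue(NA_real_, null)), 1.0)
})

test_that("empirical_pvalue is monotone non-increasing in the observed value", {
  null <- withr::with_seed(3, rnorm(500))
  obs <- seq(-3, 3, length.out = 50)
  ps <- vapply(obs, function(o) as.numeric(empirical_pvalue(o, null)),
               numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("bonferroni reproduces the printed arithmetic and caps at 1", {
  expect_equal(round(bonferroni(0.00061, 100), 2), 0.06)
  expect_equal(bonferroni(0.02, 100), 1.0)
  expect_equal(bonferroni(0.0001, 1), 0.0001)
})

test_that("pooled-null granularity resolves 1/(1 + n_perm * top_k)", {
  d <- null_dataset(60, 4, maf = 0.3, seed = 7)
  plan <- make_fold_plan(60, 10, seed = 2)
  null <- build_null(d$geno, d$trait, plan,
                     candidate_snps = d$geno$snps$snp_id,
                     n_perm = 10, top_k = 5, seed = 5)
  smallest <- as.numeric(empirical_pvalue(Inf, null))
  expect_equal(smallest, 1 / (1 + length(null$statistics)))
})

test_that("top model p-values are calibrated on null data (top_k = 1)", {
  # with top_k = 1 the observed best statistic is exchangeable with the
  # permutation bests, so P(p <= 0.05) = 5/101 exactly with 100 perms
  n_rep <- 60
  rejected <- vapply(seq_len(n_rep), function(i) {
    d <- null_dataset(300, 10, maf = 0.3, seed = 5000 + i)
    plan <- make_fold_plan(300, 10, seed = i)
    s <- exhaustive_search(d$geno, d$trait, plan,
                           candidate_snps = d$geno$snps$snp_id, top_k = 1)
    null <- build_null(d$geno, d$trait, plan,
                       candidate_snps = d$geno$snps$snp_id,
                       n_perm = 100, top_k = 1, seed = 7000 + i)
    as.numeric(empirical_pvalue(s$models$rank_stat[1], null)) <= 0.05
  }, logical(1))
  band <- binom_band(n_rep, 5 / 101)
  expect_gte(mean(rejected), band[1])
  expect_lte(mean(rejected), band[2])
})

test_that("package p-values equal a full brute-force recomputation at tiny scale", {
  # independent double-permutation oracle: pure-R search (assign_cells +
  # qmdr_t per fold) over every pair, same documented per-index
  # permutation seeding, direct counting for the p-value
  oracle_topk <- function(geno, trait, plan, top_k) {
    ids <- sort(geno$snps$snp_id)
    prs <- utils::combn(ids, 2)
    stat <- apply(prs, 2, function(pr) {
      ci <- match(pr, geno$snps$snp_id)
      g1 <- geno$calls[, ci[1]]; g2 <- geno$calls[, ci[2]]
      tt <- vapply(seq_len(plan$folds), function(f) {
        tr <- which(plan$fold != f); te <- which(plan$fold == f)
        a <- assign_cells(g1, g2, trait, tr)
        qmdr_t(a, g1, g2, trait, te)
      }, numeric(1))
      if (all(is.na(tt))) -Inf else mean(tt, na.rm = TRUE)
    })
    sort(stat, decreasing = TRUE)[seq_len(top_k)]
  }
  d <- null_dataset(60, 5, maf = 0.4, seed = 21)
  plan <- make_fold_plan(60, 10, seed = 3)
  top_k <- 3; n_perm <- 30; seed <- 13
  s <- exhaustive_search(d$geno, d$trait, plan,
                         candidate_snps = d$geno$snps$snp_id,
                         top_k = top_k)
  null <- build_null(d$geno, d$trait, plan,
                     candidate_snps = d$geno$snps$snp_id,
                     n_perm = n_perm, top_k = top_k, seed = seed)
  # oracle recomputation
  obs_or <- oracle_topk(d$geno, d$trait, plan, top_k)
  pool_or <- unlist(lapply(seq_len(n_perm), function(i) {
    perm <- withr::with_seed(epiqmdr:::child_seed(seed, i),
                             sample.int(60))
    oracle_topk(d$geno, d$trait[perm], plan, top_k)
  }))
  pool_or <- pool_or[is.finite(pool_or)]
  expect_equal(s$models$rank_stat[1], obs_or[1], tolerance = 1e-10)
  expect_equal(sort(null$statistics), sort(pool_or), tolerance = 1e-10)
  p_pkg <- as.numeric(empirical_pvalue(s$models$rank_stat[1], null))
  p_or <- (1 + sum(pool_or >= obs_or[1])) / (1 + length(pool_or))
  expect_equal(p_pkg, p_or)
})

test_that("null distributions survive a TSV round-trip", {
  d <- null_dataset(60, 4, maf = 0.3, seed = 31)
  plan <- make_fold_plan(60, 10, seed = 2)
  null <- build_null(d$geno, d$trait, plan,
                     candidate_snps = d$geno$snps$snp_id,
                     n_perm = 5, top_k = 2, seed = 5)
  path <- file.path(withr::local_tempdir(), "null.tsv")
  write_null(null, path)
  back <- read_null(path)
  expect_equal(back$statistics, null$statistics, tolerance = 1e-12)
  expect_equal(back$n_perm, null$n_perm)
  expect_equal(back$top_k, null$top_k)
})
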