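#' Cartesian coding of a two-locus genotype
#'
#' Maps the nine two-locus genotype combinations onto the integers 0-8 as
#' `3 * g1 + g2`, a bijection with `(0,0) -> 0` and `(2,2) -> 8`.
#'
#' @param g1,g2 genotype calls in `{0,1,2}` (vectorized; no missing
#'   values allowed -- exclude incomplete individuals upstream).
#' @return integer code(s) in `0..8`.
#' @export
cartesian_code <- function(g1, g2) {
  if (anyNA(g1) || anyNA(g2))
    stop("missing genotype call; exclude incomplete individuals",
         call. = FALSE)
  stopifnot(all(g1 %in% 0:2), all(g2 %in% 0:2))
  as.integer(3L * g1 + g2)
}

#' @rdname cartesian_code
#' @param code integer code(s) in `0..8`.
#' @return `cartesian_decode`: a two-column matrix `(g1, g2)`.
#' @export
cartesian_decode <- function(code) {
  stopifnot(all(code %in% 0:8))
  cbind(g1 = code %/% 3L, g2 = code %% 3L)
}

# permute x within each index group (list of index vectors); preserves
# the multiset of values per group exactly
shuffle_within_strata <- function(x, groups) {
  for (gidx in groups)
    if (length(gidx) > 1) x[gidx] <- x[gidx][sample.int(length(gidx))]
  x
}

# one-way ANOVA F of y over the distinct values of `code`;
# k = number of observed groups, df = (k-1, n-k)
anova_f_by_code <- function(y, code) {
  n <- length(y)
  grp <- match(code, sort(unique(code)))
  k <- max(grp)
  cnt <- tabulate(grp, k)
  sm <- vapply(seq_len(k), function(g) sum(y[grp == g]), numeric(1))
  m <- sum(sm) / n
  ssb <- sum(sm^2 / cnt) - n * m^2
  sst <- sum(y^2) - n * m^2
  ssw <- max(0, sst - ssb)
  if (sst <= 0) return(0)             # constant trait explains nothing
  if (ssw == 0) return(Inf)           # noiseless separation
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Overall F-statistic of the Cartesian-coded interaction regression
#'
#' Regresses the trait on the two-locus Cartesian code treated as a
#' categorical factor (up to 8 degrees of freedom against the
#' intercept-only model), i.e. a one-way ANOVA over the observed
#' two-locus genotype cells, on individuals complete for both SNPs.
#' A numeric 0-8 regressor mode (1 df) is available for comparison.
#'
#' @param trait numeric trait.
#' @param g1,g2 genotype vectors (0/1/2/NA).
#' @param coding `"categorical"` (default) or `"numeric"`.
#' @return the overall F-statistic (`Inf` for noiseless separation, 0 for
#'   a constant trait).
#' @export
interaction_f <- function(trait, g1, g2,
                          coding = c("categorical", "numeric")) {
  coding <- match.arg(coding)
  ok <- !is.na(trait) & !is.na(g1) & !is.na(g2)
  y <- trait[ok]
  code <- cartesian_code(g1[ok], g2[ok])
  k <- length(unique(code))
  if (k < 2) stop("degenerate: fewer than 2 distinct two-locus genotypes",
                  call. = FALSE)
  if (length(y) <= k)
    stop("need more samples than model degrees of freedom", call. = FALSE)
  if (coding == "categorical") return(anova_f_by_code(y, code))
  # numeric mode: simple regression slope F = t^2
  x <- as.numeric(code)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate: constant code", call. = FALSE)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  res <- y - mean(y) - b * (x - mean(x))
  s2 <- sum(res^2) / (length(y) - 2)
  if (s2 == 0) return(if (b == 0) 0 else Inf)
  (b / sqrt(s2 / sxx))^2
}

#' Explicit permutation test of epistasis for a quantitative trait
#'
#' Adaptation of the explicit test of epistasis to a quantitative
#' outcome: individuals are binned into `n_strata` trait-quantile strata
#' and, within each stratum, each SNP's genotype column is shuffled
#' independently. Per-stratum genotype frequencies (hence approximate
#' main effects) are preserved exactly while joint two-locus genotype
#' combinations are randomized. The Cartesian-coded interaction
#' F-statistic is recomputed for each permuted dataset and the p-value is
#' `(1 + #(null F >= observed F)) / (1 + n_perm)`.
#'
#' @param trait numeric trait.
#' @param g1,g2 genotype vectors (0/1/2/NA); incomplete individuals are
#'   excluded.
#' @param n_perm number of permutations (default 1000).
#' @param n_strata number of trait-quantile strata (default 10); strata
#'   with fewer than 2 members are merged with their lower neighbour.
#' @param seed RNG seed.
#' @param coding passed to [interaction_f()].
#' @return an `epistasis_test_result`: list with `observed_f`, `null_f`
#'   (length `n_perm`), `p`, `n_perm`, `n_strata` (after merging),
#'   `seed`.
#' @export
explicit_permutation_test <- function(trait, g1, g2, n_perm = 1000,
                                      n_strata = 10, seed,
                                      coding = c("categorical",
                                                 "numeric")) {
  coding <- match.arg(coding)
  stopifnot(n_perm >= 1, n_strata >= 1)
  ok <- !is.na(trait) & !is.na(g1) & !is.na(g2)
  y <- trait[ok]; a <- g1[ok]; b <- g2[ok]
  n <- length(y)
  observed <- interaction_f(y, a, b, coding = coding)
  # equal-size rank strata; merge any stratum of size < 2 downward
  strat <- as.integer(((rank(y, ties.method = "first") - 1L) *
                         n_strata) %/% n) + 1L
  sizes <- tabulate(strat, n_strata)
  while (any(sizes > 0 & sizes < 2) && sum(sizes > 0) > 1) {
    s <- which(sizes > 0 & sizes < 2)[1]
    nb <- if (any(sizes[seq_len(s - 1)] > 0))
      max(which(sizes[seq_len(s - 1)] > 0)) else
        (s + which(sizes[-seq_len(s)] > 0)[1])
    strat[strat == s] <- nb
    sizes <- tabulate(strat, n_strata)
  }
  groups <- split(seq_len(n), strat)
  null_f <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- local_seed(child_seed(seed, i), list(
      shuffle_within_strata(a, groups),
      shuffle_within_strata(b, groups)))
    null_f[i] <- tryCatch(
      interaction_f(y, perm[[1]], perm[[2]], coding = coding),
      error = function(e) NA_real_)
  }
  p <- (1 + sum(null_f >= observed, na.rm = TRUE)) / (1 + n_perm)
  structure(list(observed_f = observed, null_f = null_f, p = p,
                 n_perm = as.integer(n_perm),
                 n_strata = length(groups), seed = as.integer(seed)),
            class = "epistasis_test_result")
}

#' @export
print.epistasis_test_result <- function(x, ...) {
  cat(sprintf(
    "Explicit test of epistasis: F = %.4g, p = %.4g (%d permutations, %d strata)\n",
    x$observed_f, x$p, x$n_perm, x$n_strata))
  invisible(x)
}

#' Variance explained by SNP-SNP interactions beyond main effects
#'
#' Compares a reduced linear model (intercept + additive index SNP +
#' additive main effects of every interaction-member SNP) with a full
#' model that adds one Cartesian-coded categorical interaction term per
#' SNP pair. Reports both adjusted R-squared values, the percent increase
#' `100 * (adjR2_full - adjR2_reduced) / adjR2_reduced`, and the
#' likelihood-ratio test of the nested comparison (an F-test p-value is
#' also reported).
#'
#' @param trait numeric trait.
#' @param index_snp_calls genotype vector of the index SNP, or `NULL`.
#' @param member_snp_calls named list of genotype vectors (one per SNP
#'   appearing in any interaction).
#' @param interacting_pairs list of 2-element character vectors naming
#'   members of `member_snp_calls`.
#' @return a `variance_comparison`: list with `adj_r2_reduced`,
#'   `adj_r2_full`, `percent_increase`, `lrt_chisq`, `lrt_df`, `lrt_p`,
#'   `ftest_p`, `n`.
#' @export
variance_comparison <- function(trait, index_snp_calls = NULL,
                                member_snp_calls, interacting_pairs) {
  stopifnot(is.list(member_snp_calls), !is.null(names(member_snp_calls)))
  for (pr in interacting_pairs)
    if (!all(pr %in% names(member_snp_calls)))
      stop("pair references unknown member SNP: ",
           paste(pr, collapse = ","), call. = FALSE)
  main <- do.call(cbind, member_snp_calls)
  keep <- stats::complete.cases(trait, main)
  if (!is.null(index_snp_calls)) keep <- keep & !is.na(index_snp_calls)
  y <- trait[keep]
  X_red <- main[keep, , drop = FALSE]
  if (!is.null(index_snp_calls))
    X_red <- cbind(index_snp = index_snp_calls[keep], X_red)
  df_red <- data.frame(.y = y, X_red, check.names = TRUE)
  fit_red <- stats::lm(.y ~ ., data = df_red)
  df_full <- df_red
  for (pr in interacting_pairs) {
    code <- cartesian_code(member_snp_calls[[pr[1]]][keep],
                           member_snp_calls[[pr[2]]][keep])
    df_full[[paste0("cell_", pr[1], "_", pr[2])]] <- factor(code,
                                                            levels = 0:8)
  }
  # lm() drops aliased interaction-level columns itself (rank deficiency
  # is expected: cell factors are collinear with the additive codes)
  fit_full <- stats::lm(.y ~ ., data = df_full)
  n <- length(y)
  adj_r2 <- function(fit) summary(fit)$adj.r.squared
  rss_red <- sum(stats::residuals(fit_red)^2)
  rss_full <- sum(stats::residuals(fit_full)^2)
  df_diff <- fit_red$df.residual - fit_full$df.residual
  if (df_diff > 0 && rss_full > 0) {
    lrt <- n * (log(rss_red) - log(rss_full))
    lrt_p <- stats::pchisq(lrt, df_diff, lower.tail = FALSE)
    fstat <- ((rss_red - rss_full) / df_diff) /
      (rss_full / fit_full$df.residual)
    ftest_p <- stats::pf(fstat, df_diff, fit_full$df.residual,
                         lower.tail = FALSE)
  } else {
    lrt <- 0; lrt_p <- 1; ftest_p <- 1; df_diff <- max(0L, df_diff)
  }
  a_red <- adj_r2(fit_red); a_full <- adj_r2(fit_full)
  structure(list(adj_r2_reduced = a_red, adj_r2_full = a_full,
                 percent_increase = percent_r2_increase(a_red, a_full),
                 lrt_chisq = lrt, lrt_df = df_diff, lrt_p = lrt_p,
                 ftest_p = ftest_p, n = n),
            class = "variance_comparison")
}

#' Percent increase between two adjusted R-squared values
#'
#' `100 * (adj_r2_full - adj_r2_reduced) / adj_r2_reduced`.
#'
#' @param adj_r2_reduced,adj_r2_full adjusted R-squared of the nested
#'   models.
#' @return percent increase (0 when the two values are equal).
#' @export
percent_r2_increase <- function(adj_r2_reduced, adj_r2_full) {
  if (adj_r2_full == adj_r2_reduced) return(0)
  if (adj_r2_reduced == 0) return(NA_real_)
  100 * (adj_r2_full - adj_r2_reduced) / adj_r2_reduced
}

#' @export
print.variance_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("Variance comparison (n = %d):\n",
           "  adjusted R2 reduced: %.6f\n  adjusted R2 full:    %.6f\n",
           "  increase: %.1f%%  (LRT chi2 = %.3f, df = %d, p = %.3g)\n"),
    x$n, x$adj_r2_reduced, x$adj_r2_full, x$percent_increase,
    x$lrt_chisq, x$lrt_df, x$lrt_p))
  invisible(x)
}
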