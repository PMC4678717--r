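#' Minor allele frequency of one SNP
#'
#' @param calls integer vector of minor-allele counts in `{0,1,2,NA}`.
#' @return frequency in `[0, 0.5]`; missing calls contribute to neither
#'   numerator nor denominator.
#' @export
minor_allele_frequency <- function(calls) {
  ok <- !is.na(calls)
  if (!any(ok)) stop("all calls missing: MAF undefined", call. = FALSE)
  sum(calls[ok]) / (2 * sum(ok))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Computes the exact HWE p-value for one biallelic SNP from its genotype
#' counts: the probability, under the conditional distribution of the
#' heterozygote count given the allele counts, of all tables at most as
#' probable as the observed one (Wigginton-style exact test; no mid-p
#' refinement).
#'
#' @param n_AA,n_Aa,n_aa counts of major homozygotes, heterozygotes and
#'   minor homozygotes.
#' @return p-value in `(0, 1]`.
#' @details Probabilities are accumulated over heterozygote counts of the
#'   same parity as the minor-allele total, using the standard stable
#'   recurrence. Ties in table probability are resolved with a relative
#'   tolerance of `1e-9` so that mathematically equal tables are always
#'   pooled regardless of floating-point evaluation order.
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype", call. = FALSE)
  n_minor <- 2 * n_aa + n_Aa
  n_major <- 2 * n_AA + n_Aa
  if (n_minor > n_major) { tmp <- n_minor; n_minor <- n_major; n_major <- tmp }
  probs <- hwe_het_distribution(n, n_minor)
  p_obs <- probs[as.character(n_Aa)]
  if (is.na(p_obs)) stop("impossible heterozygote count for allele totals",
                         call. = FALSE)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# conditional P(het = h | n diploids, n_minor minor alleles) for all
# feasible h (same parity as n_minor), via the ratio recurrence
# P(h+2)/P(h) = 4*hom_min*hom_maj / ((h+2)*(h+1))
hwe_het_distribution <- function(n, n_minor) {
  if (n_minor == 0) return(stats::setNames(1, "0"))
  h_min <- n_minor %% 2L
  hs <- seq.int(h_min, n_minor, by = 2)
  h <- hs[-length(hs)]
  hom_min <- (n_minor - h) / 2
  hom_maj <- n - h - hom_min
  lp <- c(0, cumsum(log(4 * hom_min * hom_maj) - log((h + 2) * (h + 1))))
  p <- exp(lp - max(lp))
  stats::setNames(p / sum(p), hs)
}

#' Squared genotype correlation between two SNPs
#'
#' The LD measure used for pruning: the squared Pearson correlation of the
#' two 0/1/2 columns over pairwise-complete samples (composite LD; no
#' phasing required).
#'
#' @param col1,col2 integer genotype vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
genotype_r2 <- function(col1, col2) {
  ok <- !is.na(col1) & !is.na(col2)
  if (sum(ok) < 2)
    stop("need >= 2 pairwise-complete samples", call. = FALSE)
  x <- col1[ok]; y <- col2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("column constant on shared samples: r2 undefined", call. = FALSE)
  stats::cor(x, y)^2
}

#' Method-of-moments pi-hat relatedness estimate
#'
#' PLINK-style estimate of the proportion of the genome shared identical
#' by descent between two individuals, `P(IBD=1)/2 + P(IBD=2)`, from
#' identity-by-state counts and the cohort allele frequencies.
#'
#' @param g1,g2 genotype vectors (minor-allele counts) for the two
#'   individuals.
#' @param maf per-SNP minor allele frequencies (same length).
#' @param min_snps minimum number of pairwise non-missing, informative
#'   SNPs required (default 50).
#' @return pi-hat, clamped to `[0, 1]`.
#' @export
pi_hat <- function(g1, g2, maf, min_snps = 50) {
  stopifnot(length(g1) == length(g2), length(maf) == length(g1))
  ok <- !is.na(g1) & !is.na(g2) & !is.na(maf) & maf > 0 & maf < 1
  if (sum(ok) < min_snps)
    stop("insufficient data: only ", sum(ok),
         " shared informative SNPs (need ", min_snps, ")", call. = FALSE)
  p <- maf[ok]; q <- 1 - p
  ibs <- 2 - abs(g1[ok] - g2[ok])
  N0 <- sum(ibs == 0); N1 <- sum(ibs == 1); N2 <- sum(ibs == 2)
  # expected per-SNP IBS probabilities conditional on IBD state
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_ibd0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibd1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_ibd1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  m <- sum(ok)
  z0 <- N0 / e0_ibd0
  z1 <- (N1 - z0 * e1_ibd0) / e1_ibd1
  z2 <- (N2 - z0 * e2_ibd0 - z1 * e2_ibd1) / m
  z0 <- max(0, z0); z1 <- max(0, z1); z2 <- max(0, z2)
  s <- z0 + z1 + z2
  if (s > 0) { z1 <- z1 / s; z2 <- z2 / s }
  min(1, max(0, z1 / 2 + z2))
}

#' Quality-control thresholds
#'
#' Bundles the cohort QC cut-offs: minimum sample and SNP call rates,
#' the HWE exact-test p-value floor, the MAF floor, the LD pruning
#' r-squared ceiling and the pi-hat relatedness ceiling.
#'
#' @param sample_call_rate_min minimum fraction of non-missing calls per
#'   sample (default 0.90).
#' @param snp_call_rate_min minimum per-SNP call rate (default 0.95).
#' @param hwe_p_min SNPs with exact HWE p below this are removed
#'   (default 1e-7).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param ld_r2_max r-squared at or above which one SNP of a pair is
#'   pruned (default 0.6).
#' @param pihat_max pi-hat above which one individual of a pair is removed
#'   (default 0.3).
#' @param pihat_min_snps minimum shared SNPs for a pair's pi-hat to be
#'   evaluated; pairs below the floor are skipped (default 50).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.90,
                          snp_call_rate_min = 0.95,
                          hwe_p_min = 1e-7,
                          maf_min = 0.05,
                          ld_r2_max = 0.6,
                          pihat_max = 0.3,
                          pihat_min_snps = 50) {
  th <- list(sample_call_rate_min = sample_call_rate_min,
             snp_call_rate_min = snp_call_rate_min,
             hwe_p_min = hwe_p_min, maf_min = maf_min,
             ld_r2_max = ld_r2_max, pihat_max = pihat_max,
             pihat_min_snps = pihat_min_snps)
  frac <- th[setdiff(names(th), "pihat_min_snps")]
  stopifnot(all(unlist(frac) >= 0), all(unlist(frac) <= 1))
  structure(th, class = "qc_thresholds")
}

#' Apply cohort quality control
#'
#' Filters are applied in order: (1) sample call rate, (2) SNP call rate,
#' (3) HWE exact test, (4) MAF, (5) LD pruning (within each chromosome in
#' map order, the later SNP of each pair with r-squared at or above the
#' threshold is removed), (6) relatedness (for each pair with pi-hat above
#' the threshold, the member with the lower call rate is removed; ties by
#' sample-ID order).
#'
#' @param dataset a `genotype_dataset`.
#' @param thresholds a [qc_thresholds()] object.
#' @return a list with elements `dataset` (filtered) and `report`
#'   (a `qc_report` data.frame: one row per filter stage with counts of
#'   samples/SNPs removed and surviving dimensions).
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(is_genotype_dataset(dataset), inherits(thresholds, "qc_thresholds"))
  if (!length(dataset$samples) || !nrow(dataset$snps))
    stop("empty dataset", call. = FALSE)
  th <- thresholds
  stages <- list()
  log_stage <- function(name, s_rm, v_rm, d) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, samples_removed = s_rm, snps_removed = v_rm,
      samples_left = length(d$samples), snps_left = nrow(d$snps),
      stringsAsFactors = FALSE)
    if (!length(d$samples))
      stop("all samples removed at QC stage '", name, "'", call. = FALSE)
    if (!nrow(d$snps))
      stop("all SNPs removed at QC stage '", name, "'", call. = FALSE)
  }
  d <- dataset

  cr_s <- rowMeans(!is.na(d$calls))
  keep <- cr_s >= th$sample_call_rate_min
  if (!any(keep)) stop("all samples removed at QC stage 'sample_call_rate'",
                       call. = FALSE)
  d <- subset_genotypes(d, samples = which(keep))
  log_stage("sample_call_rate", sum(!keep), 0L, d)

  cr_v <- colMeans(!is.na(d$calls))
  keep <- cr_v >= th$snp_call_rate_min
  if (!any(keep)) stop("all SNPs removed at QC stage 'snp_call_rate'",
                       call. = FALSE)
  d <- subset_genotypes(d, snps = which(keep))
  log_stage("snp_call_rate", 0L, sum(!keep), d)

  hwe_p <- apply(d$calls, 2L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_pvalue(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  keep <- is.na(hwe_p) | hwe_p >= th$hwe_p_min
  if (!any(keep)) stop("all SNPs removed at QC stage 'hwe'", call. = FALSE)
  d <- subset_genotypes(d, snps = which(keep))
  log_stage("hwe", 0L, sum(!keep), d)

  maf <- apply(d$calls, 2L, function(g)
    if (all(is.na(g))) 0 else minor_allele_frequency(g))
  keep <- maf >= th$maf_min
  if (!any(keep)) stop("all SNPs removed at QC stage 'maf'", call. = FALSE)
  d <- subset_genotypes(d, snps = which(keep))
  log_stage("maf", 0L, sum(!keep), d)

  drop <- ld_prune(d, th$ld_r2_max)
  if (length(drop) == nrow(d$snps))
    stop("all SNPs removed at QC stage 'ld_prune'", call. = FALSE)
  if (length(drop)) d <- subset_genotypes(d, snps = -drop)
  log_stage("ld_prune", 0L, length(drop), d)

  drop <- relatedness_prune(d, th$pihat_max, th$pihat_min_snps)
  if (length(drop) == length(d$samples))
    stop("all samples removed at QC stage 'relatedness'", call. = FALSE)
  if (length(drop)) d <- subset_genotypes(d, samples = -drop)
  log_stage("relatedness", length(drop), 0L, d)

  report <- do.call(rbind, stages)
  class(report) <- c("qc_report", "data.frame")
  list(dataset = d, report = report)
}

# greedy within-chromosome pruning in map order: later SNP of each
# high-r2 pair removed; returns column indices to drop
ld_prune <- function(d, r2_max) {
  drop <- integer(0)
  for (chr in unique(d$snps$chrom)) {
    idx <- which(d$snps$chrom == chr)
    idx <- idx[order(d$snps$pos[idx])]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(stats::cor(d$calls[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    kept <- logical(length(idx))
    for (k in seq_along(idx)) {
      prior <- which(kept)
      if (length(prior) &&
          any(!is.na(r2[prior, k]) & r2[prior, k] >= r2_max)) {
        drop <- c(drop, idx[k])
      } else kept[k] <- TRUE
    }
  }
  sort(drop)
}

# pairwise pi-hat; of each related pair, removes the lower-call-rate
# member (ties by sample-ID order); returns row indices to drop
relatedness_prune <- function(d, pihat_max, min_snps) {
  n <- length(d$samples)
  if (n < 2 || nrow(d$snps) < min_snps) return(integer(0))
  maf <- apply(d$calls, 2L, function(g)
    if (all(is.na(g))) NA_real_ else minor_allele_frequency(g))
  cr <- rowMeans(!is.na(d$calls))
  drop <- logical(n)
  for (i in seq_len(n - 1)) {
    if (drop[i]) next
    for (j in seq.int(i + 1, n)) {
      if (drop[j]) next
      ph <- tryCatch(pi_hat(d$calls[i, ], d$calls[j, ], maf, min_snps),
                     error = function(e) NA_real_)
      if (!is.na(ph) && ph > pihat_max) {
        victim <- if (cr[i] < cr[j]) i
          else if (cr[j] < cr[i]) j
          else if (d$samples[i] <= d$samples[j]) j else i
        drop[victim] <- TRUE
        if (victim == i) break
      }
    }
  }
  which(drop)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  data.table::fwrite(as.data.frame(report), path, sep = "\t", quote = FALSE)
  invisible(path)
}
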