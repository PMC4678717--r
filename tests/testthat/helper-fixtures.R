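# Shared fixture builders and independent oracles. Everything is
# generated in code; no binary fixtures.

# tiny genotype dataset from an explicit call matrix
tiny_dataset <- function(calls, chrom = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  genotype_dataset(
    calls,
    samples = sprintf("s%02d", seq_len(nrow(calls))),
    snps = data.frame(snp_id = sprintf("rs%02d", seq_len(m)),
                      chrom = chrom %||% rep("1", m),
                      pos = pos %||% (100L * seq_len(m))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent HWE oracle: direct lgamma evaluation of the conditional
# probability of every heterozygote table given the allele counts
# (Levene/Haldane distribution), then the sum over tables at most as
# probable as the observed one (same 1e-9 relative tie tolerance as the
# implementation's documented convention).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa           # minor allele count (either allele works:
  nb <- 2 * n_AA + n_Aa           # the distribution is symmetric)
  if (na > nb) { tmp <- na; na <- nb; nb <- tmp }
  hs <- seq.int(na %% 2, na, by = 2)
  lp <- lgamma(n + 1) - lgamma((na - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma(n - hs - (na - hs) / 2 + 1) + hs * log(2) +
    lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(n_Aa, hs)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# simulate a parent-offspring genotype pair by gamete transmission at
# the given MAFs (HWE parents)
simulate_parent_offspring <- function(maf, seed) {
  withr::with_seed(seed, {
    m <- length(maf)
    parent1 <- rbinom(m, 2, maf)
    parent2 <- rbinom(m, 2, maf)
    gamete <- function(g) ifelse(g == 1, rbinom(length(g), 1, 0.5), g / 2)
    child <- gamete(parent1) + gamete(parent2)
    list(parent = as.integer(parent1), child = as.integer(child))
  })
}

# write a 3-sample x 2-SNP ped/map fixture; returns the base path and
# the expected minor-allele-coded matrix
write_pedmap_fixture <- function(dir) {
  base <- file.path(dir, "toy")
  # SNP1 alleles A/G (G minor: 2 of 6), SNP2 alleles C/T (T minor: 1 of 6)
  ped <- c("f1 s1 0 0 1 -9 A A C C",
           "f2 s2 0 0 2 -9 A G C T",
           "f3 s3 0 0 1 -9 G A C C")
  map <- c("1 rsA 0 1000", "2 rsB 0 2000")
  writeLines(ped, paste0(base, ".ped"))
  writeLines(map, paste0(base, ".map"))
  list(base = base,
       expected = matrix(c(0L, 1L, 1L, 0L, 1L, 0L), 3, 2),
       samples = c("s1", "s2", "s3"), snp_ids = c("rsA", "rsB"))
}

# minimal single-ALT VCF with one missing genotype at (sample NA2, rsV1)
write_vcf_fixture <- function(dir) {
  path <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNA1\tNA2\tNA3",
    "1\t100\trsV1\tA\tG\t.\tPASS\t.\tGT\t0/0\t./.\t0/1",
    "1\t200\trsV2\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/1\t1|1"),
    path)
  path
}

# one-pair simulated dataset with a planted pure-epistatic interaction
planted_dataset <- function(n = 1000, n_snps = 50, maf = 0.3, shift = 0.5,
                            noise_sd = 1, seed = 1,
                            pair = c(7L, 23L)) {
  M <- make_pure_epistasis_matrix(maf, shift)
  spec <- simulation_spec(
    n_samples = n, n_snps = n_snps, maf = maf, noise_sd = noise_sd,
    n_pcs = 0,
    covariate_betas = c(intercept = 0, age = 0, age2 = 0, sex = 0, pc = 0),
    interactions = list(list(snps = pair, cells = unclass(M))),
    seed = seed)
  g <- simulate_genotypes(spec)
  ph <- simulate_trait(g, spec)
  list(geno = g, trait = ph$trait, spec = spec,
       pair_ids = sort(g$snps$snp_id[pair]))
}

# null dataset: HWE genotypes, standard-normal trait, no effects
null_dataset <- function(n, n_snps, maf = 0.3, seed = 1) {
  spec <- simulation_spec(
    n_samples = n, n_snps = n_snps, maf = maf, noise_sd = 1, n_pcs = 0,
    covariate_betas = c(intercept = 0, age = 0, age2 = 0, sex = 0, pc = 0),
    seed = seed)
  g <- simulate_genotypes(spec)
  ph <- simulate_trait(g, spec)
  list(geno = g, trait = ph$trait)
}

# 99% binomial acceptance band for an observed proportion
binom_band <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p) / n
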