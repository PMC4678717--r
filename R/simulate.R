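#' Simulation specification for two-locus quantitative-trait data
#'
#' Describes a synthetic cohort: biallelic SNPs in Hardy-Weinberg
#' equilibrium at chosen minor allele frequencies, a Gaussian trait built
#' from covariate effects (age, age-squared, sex, principal components,
#' an optional index SNP), additive per-SNP effects, 3x3 two-locus
#' cell-mean interaction effects and Gaussian noise, with controllable
#' uniform missingness.
#'
#' Defaults emulate an adult BMI cohort: age uniform on 20-80 years, sex
#' Bernoulli(0.5), three standard-normal ancestry PCs, intercept 27
#' kg/m^2, age effect 0.05 and age-squared -5e-4 per year, sex effect -1,
#' PC effects 0.5, index-SNP effect 0.4 per allele, residual SD 4.
#'
#' @param n_samples,n_snps cohort dimensions.
#' @param maf per-SNP minor allele frequencies in `(0, 0.5]`; a scalar is
#'   recycled; default evenly spaced on `[0.05, 0.5]`.
#' @param missing_rate per-call missingness probability in `[0, 1)`.
#' @param age_range uniform age range (years).
#' @param n_pcs number of standard-normal principal-component covariates.
#' @param covariate_betas named vector with elements `intercept`, `age`,
#'   `age2`, `sex` and `pc` (shared across PCs).
#' @param index_snp optional column index of an index SNP with additive
#'   effect `index_beta` on the raw trait.
#' @param index_beta additive effect of the index SNP (trait units per
#'   minor allele).
#' @param additive_beta numeric vector of per-SNP additive effects
#'   (length `n_snps`; default all zero).
#' @param interactions list of `list(snps = c(i, j), cells = 3x3 matrix)`
#'   cell-mean offsets added for genotype `(g1, g2)` via
#'   `cells[g1 + 1, g2 + 1]`.
#' @param noise_sd Gaussian noise SD (trait units).
#' @param seed RNG seed (required).
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_samples = 1000, n_snps = 50, maf = NULL,
                            missing_rate = 0, age_range = c(20, 80),
                            n_pcs = 3,
                            covariate_betas = c(intercept = 27,
                                                age = 0.05, age2 = -5e-4,
                                                sex = -1, pc = 0.5),
                            index_snp = NULL, index_beta = 0.4,
                            additive_beta = NULL, interactions = list(),
                            noise_sd = 4, seed) {
  maf <- maf %||% seq(0.05, 0.5, length.out = n_snps)
  maf <- rep_len(maf, n_snps)
  stopifnot(all(maf > 0), all(maf <= 0.5),
            missing_rate >= 0, missing_rate < 1,
            is.finite(noise_sd), noise_sd >= 0)
  additive_beta <- additive_beta %||% numeric(n_snps)
  stopifnot(length(additive_beta) == n_snps)
  for (it in interactions) {
    stopifnot(length(it$snps) == 2, all(it$snps %in% seq_len(n_snps)),
              is.matrix(it$cells), all(dim(it$cells) == c(3, 3)),
              all(is.finite(it$cells)))
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps), maf = maf,
                 missing_rate = missing_rate, age_range = age_range,
                 n_pcs = as.integer(n_pcs),
                 covariate_betas = covariate_betas,
                 index_snp = index_snp, index_beta = index_beta,
                 additive_beta = additive_beta,
                 interactions = interactions, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP is drawn independently (no LD) with genotype probabilities
#' `((1-p)^2, 2p(1-p), p^2)` at its MAF `p`; missingness is applied
#' uniformly at random at `spec$missing_rate`.
#'
#' @param spec a [simulation_spec()].
#' @return a [genotype_dataset()] with SNP IDs `snp0001 ...`, all on
#'   chromosome `"1"` at 10-kb spacing.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_samples; m <- spec$n_snps
  calls <- local_seed(child_seed(spec$seed, 1L), {
    g <- vapply(seq_len(m), function(j) {
      p <- spec$maf[j]
      sample.int(3L, n, replace = TRUE,
                 prob = c((1 - p)^2, 2 * p * (1 - p), p^2)) - 1L
    }, integer(n))
    if (spec$missing_rate > 0)
      g[stats::runif(length(g)) < spec$missing_rate] <- NA_integer_
    g
  })
  snps <- data.frame(snp_id = sprintf("snp%04d", seq_len(m)),
                     chrom = "1", pos = 10000L * seq_len(m),
                     stringsAsFactors = FALSE)
  genotype_dataset(calls, sprintf("ind%05d", seq_len(n)), snps)
}

#' Simulate the quantitative trait and covariates
#'
#' Builds `trait = intercept + covariate terms + index-SNP effect +
#' additive SNP effects + interaction cell offsets + N(0, noise_sd)`.
#' Missing genotype calls contribute zero to the genetic terms.
#'
#' @param genotypes a `genotype_dataset` (normally from
#'   [simulate_genotypes()]).
#' @param spec the same [simulation_spec()].
#' @return a [phenotype_table()] with covariates `age`, `age2`, `sex`,
#'   `pc1..pcK`.
#' @export
simulate_trait <- function(genotypes, spec) {
  stopifnot(inherits(spec, "simulation_spec"),
            is_genotype_dataset(genotypes),
            nrow(genotypes$snps) == spec$n_snps)
  n <- length(genotypes$samples)
  b <- spec$covariate_betas
  local_seed(child_seed(spec$seed, 2L), {
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    sex <- stats::rbinom(n, 1, 0.5)
    pcs <- if (spec$n_pcs > 0)
      matrix(stats::rnorm(n * spec$n_pcs), n) else
        matrix(numeric(0), n, 0)
    y <- b[["intercept"]] + b[["age"]] * age + b[["age2"]] * age^2 +
      b[["sex"]] * sex
    if (spec$n_pcs > 0) y <- y + pcs %*% rep(b[["pc"]], spec$n_pcs)
    G0 <- genotypes$calls
    G0[is.na(G0)] <- 0L
    if (!is.null(spec$index_snp))
      y <- y + spec$index_beta * G0[, spec$index_snp]
    if (any(spec$additive_beta != 0))
      y <- y + G0 %*% spec$additive_beta
    for (it in spec$interactions) {
      off <- it$cells[cbind(G0[, it$snps[1]] + 1L,
                            G0[, it$snps[2]] + 1L)]
      off[is.na(genotypes$calls[, it$snps[1]]) |
            is.na(genotypes$calls[, it$snps[2]])] <- 0
      y <- y + off
    }
    y <- as.numeric(y) + stats::rnorm(n, 0, spec$noise_sd)
    cov <- data.frame(age = age, age2 = age^2, sex = sex)
    if (spec$n_pcs > 0) {
      pcs <- as.data.frame(pcs)
      names(pcs) <- paste0("pc", seq_len(spec$n_pcs))
      cov <- cbind(cov, pcs)
    }
    phenotype_table(genotypes$samples, y, cov)
  })
}

#' Pure-epistasis cell-mean matrix
#'
#' Constructs a 3x3 two-locus cell-mean offset matrix with exactly zero
#' HWE-weighted marginal (additive) effects at the given MAF: an XOR-like
#' pattern is double-centered with HWE genotype weights and rescaled so
#' that the HWE-weighted standard deviation of the cell offsets equals
#' `shift`. A pair of SNPs carrying this matrix has no marginal
#' single-SNP effect yet a strong 9-cell interaction.
#'
#' @param maf minor allele frequency in `(0, 0.5]` (both SNPs).
#' @param shift HWE-weighted SD of the offsets, in trait units.
#' @return a 3x3 matrix (class `pure_epistasis_matrix`), row = genotype
#'   of SNP 1, column = genotype of SNP 2.
#' @export
make_pure_epistasis_matrix <- function(maf, shift) {
  stopifnot(maf > 0, maf <= 0.5, is.finite(shift))
  w <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  m0 <- outer(0:2, 0:2, function(a, b) as.numeric((a + b) %% 2 == 1))
  rm_ <- as.numeric(m0 %*% w)          # weighted row means
  cm_ <- as.numeric(t(m0) %*% w)       # weighted column means
  gm <- sum(w * rm_)
  m <- m0 - outer(rm_, rep(1, 3)) - outer(rep(1, 3), cm_) + gm
  sd_w <- sqrt(sum(outer(w, w) * m^2))
  m <- if (shift == 0 || sd_w == 0) m * 0 else m * (shift / sd_w)
  structure(m, class = c("pure_epistasis_matrix", "matrix", "array"),
            maf = maf, shift = shift)
}

#' Write a complete simulated fixture directory
#'
#' Emits `genotypes.tsv` (dosage matrix) and `phenotypes.tsv` for a
#' simulation spec, the same formats [read_genotypes()] and
#' [read_phenotypes()] consume.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_directory <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- simulate_genotypes(spec)
  ph <- simulate_trait(g, spec)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  write_genotypes(g, paths[["genotypes"]])
  data.table::fwrite(as.data.frame(ph)[, setdiff(names(ph),
                                                 "residual_trait")],
                     paths[["phenotypes"]], sep = "\t", quote = FALSE)
  invisible(paths)
}
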