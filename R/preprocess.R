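#' Phenotype table
#'
#' Per-sample quantitative trait plus covariates. Retained samples must be
#' complete for the trait and every covariate; `residual_trait` is filled
#' by [residualize_trait()].
#'
#' @param sample_id character vector of sample IDs.
#' @param trait numeric raw trait (e.g. BMI in kg/m^2).
#' @param covariates data.frame of named numeric covariate columns (may
#'   have zero columns).
#' @return a `phenotype_table` (data.frame with attribute `covariate_names`).
#' @export
phenotype_table <- function(sample_id, trait, covariates = NULL) {
  sample_id <- as.character(sample_id)
  if (is.null(covariates))
    covariates <- data.frame(row.names = seq_along(sample_id))
  covariates <- as.data.frame(covariates)
  stopifnot(length(trait) == length(sample_id),
            nrow(covariates) %in% c(0L, length(sample_id)))
  if (anyDuplicated(sample_id)) stop("duplicate sample IDs", call. = FALSE)
  bad <- !stats::complete.cases(cbind(trait, covariates))
  if (any(bad))
    stop("incomplete phenotype data for sample(s): ",
         paste(utils::head(sample_id[bad], 5), collapse = ", "),
         " (complete trait and covariates are required)", call. = FALSE)
  out <- data.frame(sample_id = sample_id, trait = trait,
                    covariates, residual_trait = NA_real_,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "covariate_names") <- names(covariates)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Read a phenotype/covariate TSV
#'
#' Expects columns `sample_id`, `trait`, and any number of numeric
#' covariate columns.
#'
#' @param path TSV path.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("sample_id", "trait") %in% names(dt)))
    stop("phenotype TSV needs 'sample_id' and 'trait' columns: ", path,
         call. = FALSE)
  cov <- setdiff(names(dt), c("sample_id", "trait", "residual_trait"))
  phenotype_table(dt$sample_id, dt$trait,
                  as.data.frame(dt[, cov, with = FALSE]))
}

#' Residualize the trait on covariates (and an optional index SNP)
#'
#' Fits ordinary least squares of the raw trait on an intercept, the named
#' covariate columns and, if given, the additive genotype of an index SNP,
#' and stores the residuals in `residual_trait`. The residuals are the
#' continuous outcome used by every downstream stage.
#'
#' @param table a [phenotype_table()].
#' @param covariate_names character vector of covariate columns to adjust
#'   for (default: all covariates in the table).
#' @param genotypes optional `genotype_dataset` supplying the index SNP.
#' @param index_snp optional SNP ID whose additive code joins the design;
#'   samples with a missing index genotype are dropped.
#' @return the table with `residual_trait` populated (and an
#'   `adjustment_fit` attribute holding the `lm` coefficients).
#' @export
residualize_trait <- function(table, covariate_names = NULL,
                              genotypes = NULL, index_snp = NULL) {
  stopifnot(inherits(table, "phenotype_table"))
  if (is.null(covariate_names))
    covariate_names <- attr(table, "covariate_names")
  miss <- setdiff(covariate_names, names(table))
  if (length(miss))
    stop("unknown covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(table[, covariate_names, drop = FALSE])
  if (!is.null(index_snp)) {
    stopifnot(is_genotype_dataset(genotypes))
    ci <- match(index_snp, genotypes$snps$snp_id)
    if (is.na(ci)) stop("index SNP not in dataset: ", index_snp,
                        call. = FALSE)
    g <- genotypes$calls[match(table$sample_id, genotypes$samples), ci]
    if (anyNA(g)) {
      keep <- !is.na(g)
      table <- table[keep, , drop = FALSE]
      class(table) <- c("phenotype_table", "data.frame")
      X <- X[keep, , drop = FALSE]
      g <- g[keep]
    }
    X <- cbind(X, index_snp = as.numeric(g))
  }
  df <- data.frame(.y = table$trait, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    dep <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design: dependent column(s) ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  table$residual_trait <- as.numeric(stats::residuals(fit))
  attr(table, "adjustment_fit") <- stats::coef(fit)
  attr(table, "covariate_names") <- attr(table, "covariate_names")
  table
}

#' Per-SNP additive main-effect scan
#'
#' Simple linear regression of the residualized trait on each SNP's
#' additive genotype (intercept + slope); two-sided p-value from the
#' slope's t distribution with n-2 degrees of freedom. Monomorphic SNPs
#' (or SNPs with fewer than 3 called samples) are flagged and get `NA`
#' statistics.
#'
#' @param genotypes a `genotype_dataset`.
#' @param residual_trait numeric vector aligned with `genotypes$samples`.
#' @return a `main_effect_scan` data.frame: `snp_id`, `beta`, `se`, `p`,
#'   `n`, `monomorphic`.
#' @export
main_effect_scan <- function(genotypes, residual_trait) {
  stopifnot(is_genotype_dataset(genotypes),
            length(residual_trait) == length(genotypes$samples))
  G <- genotypes$calls
  m <- ncol(G)
  beta <- se <- p <- rep(NA_real_, m)
  nn <- integer(m)
  mono <- logical(m)
  for (j in seq_len(m)) {
    g <- G[, j]
    ok <- !is.na(g) & !is.na(residual_trait)
    nj <- sum(ok)
    nn[j] <- nj
    if (nj < 3 || length(unique(g[ok])) < 2) { mono[j] <- TRUE; next }
    x <- as.numeric(g[ok]); y <- residual_trait[ok]
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    res <- y - mean(y) - b * (x - mean(x))
    s2 <- sum(res^2) / (nj - 2)
    beta[j] <- b
    se[j] <- sqrt(s2 / sxx)
    p[j] <- if (se[j] == 0) 0 else
      2 * stats::pt(abs(b / se[j]), df = nj - 2, lower.tail = FALSE)
  }
  out <- data.frame(snp_id = genotypes$snps$snp_id, beta = beta, se = se,
                    p = p, n = nn, monomorphic = mono,
                    stringsAsFactors = FALSE)
  class(out) <- c("main_effect_scan", "data.frame")
  out
}

#' Main-effect candidate filter
#'
#' Retains SNPs whose scan p-value is strictly below the cutoff,
#' returned in ascending-p order. SNPs flagged monomorphic (p undefined)
#' are never retained.
#'
#' @param scan a [main_effect_scan()] result.
#' @param cutoff p-value cutoff (strict `<`; default 0.016).
#' @return character vector of SNP IDs.
#' @export
main_effect_filter <- function(scan, cutoff = 0.016) {
  stopifnot(inherits(scan, "main_effect_scan"), nrow(scan) > 0)
  hit <- !is.na(scan$p) & scan$p < cutoff
  scan$snp_id[hit][order(scan$p[hit])]
}
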