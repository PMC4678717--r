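#' Genotype dataset container
#'
#' A `genotype_dataset` holds a sample-by-SNP matrix of minor-allele counts
#' together with sample identifiers and per-SNP metadata. Calls are coded
#' 0/1/2 = number of copies of the dataset-wide minor allele; missing calls
#' are `NA`. This is the additive coding assumed by the main-effect scan,
#' the MAF filter and the QMDR cell grid.
#'
#' @param calls integer matrix, `n_samples x n_snps`, values in `{0,1,2,NA}`.
#'   Row and column names, if present, are overridden by `samples`/`snps`.
#' @param samples character vector of unique sample IDs (rows of `calls`).
#' @param snps `data.frame` with one row per SNP and columns `snp_id`,
#'   `chrom`, `pos` (1-based) and optionally `gene`.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `calls`, `samples`, `snps`.
#' @examples
#' g <- genotype_dataset(matrix(c(0L, 1L, 2L, 0L), 2, 2),
#'                       samples = c("s1", "s2"),
#'                       snps = data.frame(snp_id = c("rs1", "rs2"),
#'                                         chrom = "1", pos = c(100L, 200L)))
#' dim(g$calls)
#' @export
genotype_dataset <- function(calls, samples, snps) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.character(samples)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "chrom", "pos") %in% names(snps)))
    stop("`snps` must have columns snp_id, chrom, pos", call. = FALSE)
  if (!("gene" %in% names(snps))) snps$gene <- NA_character_
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  obj <- structure(list(calls = calls, samples = samples, snps = snps),
                   class = "genotype_dataset")
  validate_genotype_dataset(obj)
}

#' @rdname genotype_dataset
#' @param x object to validate or test.
#' @export
validate_genotype_dataset <- function(x) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (nrow(x$calls) != length(x$samples))
    stop("calls has ", nrow(x$calls), " rows but there are ",
         length(x$samples), " samples", call. = FALSE)
  if (ncol(x$calls) != nrow(x$snps))
    stop("calls has ", ncol(x$calls), " columns but there are ",
         nrow(x$snps), " SNPs", call. = FALSE)
  if (anyDuplicated(x$samples))
    stop("duplicate sample IDs", call. = FALSE)
  if (anyDuplicated(x$snps$snp_id))
    stop("duplicate SNP IDs", call. = FALSE)
  v <- x$calls[!is.na(x$calls)]
  if (length(v) && (min(v) < 0L || max(v) > 2L))
    stop("non-missing calls must be 0, 1 or 2", call. = FALSE)
  dimnames(x$calls) <- list(x$samples, x$snps$snp_id)
  x
}

#' @rdname genotype_dataset
#' @export
is_genotype_dataset <- function(x) inherits(x, "genotype_dataset")

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$samples), "samples x",
      nrow(x$snps), "SNPs\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Subset a genotype dataset
#'
#' @param x a `genotype_dataset`.
#' @param samples sample IDs or row indices to keep (default all).
#' @param snps SNP IDs or column indices to keep (default all).
#' @return the subsetted `genotype_dataset`.
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  stopifnot(is_genotype_dataset(x))
  ri <- seq_along(x$samples)
  ci <- seq_len(nrow(x$snps))
  if (!is.null(samples))
    ri <- if (is.character(samples)) match(samples, x$samples) else samples
  if (!is.null(snps))
    ci <- if (is.character(snps)) match(snps, x$snps$snp_id) else snps
  if (anyNA(ri)) stop("unknown sample ID(s)", call. = FALSE)
  if (anyNA(ci)) stop("unknown SNP ID(s)", call. = FALSE)
  genotype_dataset(x$calls[ri, ci, drop = FALSE],
                   x$samples[ri], x$snps[ci, , drop = FALSE])
}
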