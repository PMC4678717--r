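#' Read genotypes from PLINK ped/map, VCF or a TSV dosage matrix
#'
#' All formats are recoded on input to counts of the dataset-wide minor
#' allele, determined from the allele frequencies observed in the file
#' itself: a column whose coded allele has frequency above 0.5 is flipped
#' (`g -> 2 - g`). On an exact 0.5 tie the coding in the file is kept for
#' matrix input; for allele-character input (ped) the lexicographically
#' later allele is counted.
#'
#' @param path path to the genotype file. For `format = "ped_map"` this is
#'   the `.ped` file; the `.map` file is found by swapping the extension
#'   (or pass a path without extension).
#' @param format one of `"ped_map"`, `"vcf"`, `"tsv_matrix"`.
#' @return a [genotype_dataset()].
#' @details
#' * **ped/map**: whitespace-delimited PLINK text pedigree. Columns 1-6 are
#'   FID, IID, father, mother, sex, phenotype; then two allele characters
#'   per SNP, `0` = missing. Sample IDs are taken from the IID column.
#' * **VCF**: only the GT field is used (separators `/` or `|`); `.`
#'   alleles give a missing call. Multi-allelic records are rejected.
#'   Requires the VariantAnnotation package.
#' * **tsv_matrix**: first column `sample_id`, remaining columns one per
#'   SNP (header = SNP IDs), cells 0/1/2 or NA. Chromosome/position
#'   metadata are not carried by this format and are filled with
#'   placeholder values (`chrom = "un"`, `pos` = column index).
#' @seealso [write_genotypes()] for the TSV writer; round-tripping a
#'   dataset through `write_genotypes()`/`read_genotypes()` preserves the
#'   call matrix.
#' @export
read_genotypes <- function(path, format = c("tsv_matrix", "ped_map", "vcf")) {
  format <- match.arg(format)
  switch(format,
         tsv_matrix = read_genotypes_tsv(path),
         ped_map    = read_genotypes_pedmap(path),
         vcf        = read_genotypes_vcf(path))
}

#' Write a genotype dataset as a TSV dosage matrix
#'
#' @param x a `genotype_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(is_genotype_dataset(x))
  dt <- data.table::as.data.table(x$calls)
  data.table::setnames(dt, x$snps$snp_id)
  dt <- cbind(data.table::data.table(sample_id = x$samples), dt)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

flip_to_minor <- function(calls) {
  ## column-wise: if coded-allele frequency > 0.5, count the other allele
  f <- colMeans(calls, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) calls[, flip] <- 2L - calls[, flip, drop = FALSE]
  calls
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  if (!ncol(dt) || names(dt)[1] != "sample_id")
    stop("TSV matrix must have a leading 'sample_id' column: ", path,
         call. = FALSE)
  samples <- as.character(dt[[1]])
  calls <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(calls) <- "integer"
  bad <- which(!is.na(calls) & !(calls %in% 0:2), arr.ind = TRUE)
  if (nrow(bad))
    stop("parse error in ", path, " near data line ", bad[1, 1],
         ": cell value not in {0,1,2,NA}", call. = FALSE)
  calls <- flip_to_minor(calls)
  snps <- data.frame(snp_id = colnames(dt)[-1], chrom = "un",
                     pos = seq_len(ncol(calls)), stringsAsFactors = FALSE)
  genotype_dataset(calls, samples, snps)
}

read_genotypes_pedmap <- function(path) {
  base <- sub("\\.ped$", "", path)
  ped_path <- paste0(base, ".ped")
  map_path <- paste0(base, ".map")
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  expected <- 6L + 2L * m
  if (ncol(ped) != expected)
    stop("dimension error: ", ped_path, " has ", ncol(ped),
         " columns but the map implies ", expected, call. = FALSE)
  samples <- ped[[2]]
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  calls <- matrix(NA_integer_, nrow(ped), m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    if (!length(obs)) next  # all-missing SNP stays NA
    tab <- sort(table(obs))
    alleles <- names(tab)
    if (length(alleles) > 2L)
      stop("parse error in ", ped_path, ": SNP ", map$snp_id[j],
           " has >2 alleles", call. = FALSE)
    # minor = least frequent; exact tie -> lexicographically later allele
    minor <- if (length(alleles) == 1L) {
      NA_character_  # monomorphic: all calls are 0 copies of (absent) minor
    } else if (tab[1] == tab[2]) {
      sort(alleles)[2]
    } else alleles[1]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    cnt <- (!is.na(minor)) * ((a1[, j] == minor) + (a2[, j] == minor))
    cnt[miss] <- NA_integer_
    calls[, j] <- as.integer(cnt)
  }
  snps <- map[, c("snp_id", "chrom", "pos")]
  genotype_dataset(calls, samples, snps)
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT  # variants x samples
  if (is.null(gt)) stop("parse error: VCF has no GT field: ", path,
                        call. = FALSE)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) > 1L))
    stop("parse error: multi-allelic VCF records are not supported",
         call. = FALSE)
  code1 <- c("0" = 0L, "1" = 1L)
  parse_gt <- function(s) {
    parts <- strsplit(s, "[/|]", perl = TRUE)
    vapply(parts, function(p) {
      if (any(p == ".") || length(p) != 2L) return(NA_integer_)
      v <- code1[p]
      if (anyNA(v)) return(NA_integer_)
      sum(v)
    }, integer(1))
  }
  calls <- matrix(parse_gt(as.vector(gt)), nrow = nrow(gt))  # var x samp
  calls <- t(calls)                                          # samp x var
  calls <- flip_to_minor(calls)
  rr <- SummarizedExperiment::rowRanges(vcf)
  snps <- data.frame(snp_id = rownames(gt),
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     stringsAsFactors = FALSE)
  genotype_dataset(calls, colnames(gt), snps)
}
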