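#' Gene-gene knowledge models and the implication index
#'
#' A gene-gene model records, for each gene of a putative interacting
#' pair, the set of knowledge sources (e.g. pathway, ontology or
#' protein-interaction databases) supporting that gene's membership in
#' the relationship. Its implication index is the sum of the two source
#' counts; models with a high index are considered biologically
#' plausible candidates for epistasis.
#'
#' @param gene_a,gene_b gene symbols (must differ).
#' @param sources_a,sources_b character vectors of supporting source
#'   names (duplicates ignored).
#' @return a `gene_gene_model` list with an `implication_index` field.
#' @export
gene_gene_model <- function(gene_a, gene_b, sources_a = character(),
                            sources_b = character()) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  if (identical(gene_a, gene_b))
    stop("gene_a and gene_b must differ", call. = FALSE)
  sources_a <- unique(as.character(sources_a))
  sources_b <- unique(as.character(sources_b))
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 sources_a = sources_a, sources_b = sources_b,
                 implication_index = length(sources_a) + length(sources_b)),
            class = "gene_gene_model")
}

#' @rdname gene_gene_model
#' @param model a `gene_gene_model`.
#' @export
implication_index <- function(model) {
  stopifnot(inherits(model, "gene_gene_model"))
  length(model$sources_a) + length(model$sources_b)
}

#' Read a gene-gene knowledge table
#'
#' One row per gene-per-source support: columns `gene_a`, `gene_b`,
#' `gene` (which member the row supports) and `source`. Rows sharing the
#' same unordered gene pair are aggregated into one model.
#'
#' @param path TSV path.
#' @return list of [gene_gene_model()] objects.
#' @export
read_knowledge_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("gene_a", "gene_b", "gene", "source")
  if (!all(need %in% names(dt)))
    stop("knowledge TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  a <- pmin(dt$gene_a, dt$gene_b)
  b <- pmax(dt$gene_a, dt$gene_b)
  key <- paste(a, b, sep = "\r")
  lapply(split(seq_len(nrow(dt)), key), function(i) {
    ga <- a[i[1]]; gb <- b[i[1]]
    gene_gene_model(ga, gb,
                    sources_a = dt$source[i][dt$gene[i] == ga],
                    sources_b = dt$source[i][dt$gene[i] == gb])
  })
}

#' Filter gene-gene models by implication index
#'
#' @param models list of [gene_gene_model()] objects.
#' @param min_index retain models with `implication_index >= min_index`
#'   (inclusive; default 5).
#' @return the retained models.
#' @export
filter_gene_models <- function(models, min_index = 5) {
  Filter(function(m) implication_index(m) >= min_index, models)
}

#' Read a SNP-to-gene map
#'
#' @param path TSV with columns `snp_id`, `gene` (many SNPs per gene).
#' @param dataset optional `genotype_dataset`; mapped SNPs absent from it
#'   are dropped with a warning.
#' @return named character vector: `snp_id -> gene`.
#' @export
read_snp_gene_map <- function(path, dataset = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("snp_id", "gene") %in% names(dt)))
    stop("SNP-gene TSV needs columns snp_id, gene", call. = FALSE)
  map <- stats::setNames(as.character(dt$gene), as.character(dt$snp_id))
  if (!is.null(dataset)) {
    stopifnot(is_genotype_dataset(dataset))
    absent <- setdiff(names(map), dataset$snps$snp_id)
    if (length(absent)) {
      warning("dropping ", length(absent),
              " mapped SNP(s) absent from the dataset", call. = FALSE)
      map <- map[setdiff(names(map), absent)]
    }
  }
  map
}

#' Expand gene-gene models to candidate SNP-SNP pairs
#'
#' Takes the Cartesian product of the SNPs mapped to each gene of every
#' model, excludes self-pairs, canonicalizes pair order (lexicographic by
#' SNP ID) and deduplicates. Models with a gene that maps to no SNP are
#' skipped with a warning.
#'
#' @param gene_models list of [gene_gene_model()] objects.
#' @param snp_gene_map named character vector `snp_id -> gene`
#'   (see [read_snp_gene_map()]).
#' @return two-column character matrix of SNP pairs (`snp1 < snp2`).
#' @export
expand_to_snp_models <- function(gene_models, snp_gene_map) {
  if (!length(snp_gene_map)) stop("empty SNP-gene map", call. = FALSE)
  by_gene <- split(names(snp_gene_map), snp_gene_map)
  out <- list()
  for (m in gene_models) {
    sa <- by_gene[[m$gene_a]]; sb <- by_gene[[m$gene_b]]
    if (is.null(sa) || is.null(sb)) {
      warning("gene model ", m$gene_a, "-", m$gene_b,
              " skipped: gene with no mapped SNPs", call. = FALSE)
      next
    }
    gr <- expand.grid(s1 = sa, s2 = sb, stringsAsFactors = FALSE)
    gr <- gr[gr$s1 != gr$s2, , drop = FALSE]
    if (nrow(gr)) out[[length(out) + 1L]] <-
        cbind(pmin(gr$s1, gr$s2), pmax(gr$s1, gr$s2))
  }
  if (!length(out))
    return(matrix(character(0), 0, 2,
                  dimnames = list(NULL, c("snp1", "snp2"))))
  pairs <- do.call(rbind, out)
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("snp1", "snp2"))
  pairs
}
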