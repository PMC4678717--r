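#' Pipeline configuration
#'
#' Bundles file paths, QC thresholds and stage settings for
#' [run_discovery()] / [run_directed()]. Any field can be overridden; the
#' remaining fields take the defaults below (which mirror the analysis'
#' canonical settings: main-effect cutoff 0.016, implication index 5,
#' 10-fold QMDR with top 100 models, 1000 permutations, explicit-test
#' carry-forward at Bonferroni p < 0.1).
#'
#' @param genotype_file,genotype_format,phenotype_file input files;
#'   format as in [read_genotypes()].
#' @param knowledge_file,snp_gene_file optional knowledge-filter inputs.
#' @param out_dir output directory.
#' @param qc a [qc_thresholds()] object.
#' @param covariates covariate column names (`NULL` = all in the
#'   phenotype table).
#' @param index_snp optional index-SNP ID adjusted for in
#'   residualization.
#' @param filter_mode `"main_effect"`, `"knowledge"` or `"both"` (union
#'   of the two candidate sets).
#' @param main_effect_cutoff strict p-value cutoff for the main-effect
#'   screen.
#' @param min_implication_index inclusive implication-index cutoff.
#' @param folds,top_k,seed,rank_by,empty_cell_policy QMDR settings.
#' @param n_perm permutations for the search null.
#' @param epi_n_perm,epi_n_strata,epi_coding explicit-test settings.
#' @param carry_bonferroni_max models with Bonferroni p strictly below
#'   this enter the explicit-epistasis / variance stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genotype_file, phenotype_file,
                            genotype_format = "tsv_matrix",
                            knowledge_file = NULL, snp_gene_file = NULL,
                            out_dir = ".",
                            qc = qc_thresholds(),
                            covariates = NULL, index_snp = NULL,
                            filter_mode = c("main_effect", "knowledge",
                                            "both"),
                            main_effect_cutoff = 0.016,
                            min_implication_index = 5,
                            folds = 10, top_k = 100, seed,
                            rank_by = "mean", empty_cell_policy = "low",
                            n_perm = 1000,
                            epi_n_perm = 1000, epi_n_strata = 10,
                            epi_coding = "categorical",
                            carry_bonferroni_max = 0.1) {
  filter_mode <- match.arg(filter_mode)
  if (filter_mode != "main_effect" &&
      (is.null(knowledge_file) || is.null(snp_gene_file)))
    stop("knowledge filter requires knowledge_file and snp_gene_file",
         call. = FALSE)
  for (f in c(genotype_file, phenotype_file, knowledge_file,
              snp_gene_file))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  structure(list(genotype_file = genotype_file,
                 genotype_format = genotype_format,
                 phenotype_file = phenotype_file,
                 knowledge_file = knowledge_file,
                 snp_gene_file = snp_gene_file, out_dir = out_dir,
                 qc = qc, covariates = covariates,
                 index_snp = index_snp, filter_mode = filter_mode,
                 main_effect_cutoff = main_effect_cutoff,
                 min_implication_index = min_implication_index,
                 folds = folds, top_k = top_k, seed = as.integer(seed),
                 rank_by = rank_by,
                 empty_cell_policy = empty_cell_policy, n_perm = n_perm,
                 epi_n_perm = epi_n_perm, epi_n_strata = epi_n_strata,
                 epi_coding = epi_coding,
                 carry_bonferroni_max = carry_bonferroni_max),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key=value file
#'
#' Lines of the form `key = value`; `#` starts a comment; numeric-looking
#' values are converted. Keys match the [pipeline_config()] arguments,
#' with QC thresholds as `qc.<name>`.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("bad config line: ", lines[bad][1], call. = FALSE)
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, character(1), 1)
  qc_keys <- grep("^qc\\.", names(vals), value = TRUE)
  qc_args <- vals[qc_keys]
  names(qc_args) <- sub("^qc\\.", "", names(qc_args))
  vals <- vals[setdiff(names(vals), qc_keys)]
  if (length(qc_args)) vals$qc <- do.call(qc_thresholds, qc_args)
  do.call(pipeline_config, vals)
}

# load inputs, apply QC, align phenotype, residualize; shared by both
# pipeline modes
pipeline_prepare <- function(config, manifest) {
  t0 <- proc.time()[["elapsed"]]
  geno <- read_genotypes(config$genotype_file, config$genotype_format)
  pheno <- read_phenotypes(config$phenotype_file)
  manifest$stages$input <- list(samples = length(geno$samples),
                                snps = nrow(geno$snps))
  qc <- apply_qc(geno, config$qc)
  geno <- qc$dataset
  common <- intersect(geno$samples, pheno$sample_id)
  if (!length(common)) stop("no samples shared by genotypes and phenotypes",
                            call. = FALSE)
  geno <- subset_genotypes(geno, samples = common)
  pheno <- pheno[match(common, pheno$sample_id), , drop = FALSE]
  class(pheno) <- c("phenotype_table", "data.frame")
  pheno <- residualize_trait(pheno, config$covariates, geno,
                             config$index_snp)
  if (nrow(pheno) < length(geno$samples))  # index-SNP missingness
    geno <- subset_genotypes(geno, samples = pheno$sample_id)
  manifest$stages$qc <- list(samples = length(geno$samples),
                             snps = nrow(geno$snps),
                             report = as.data.frame(qc$report))
  manifest$wall$prepare <- proc.time()[["elapsed"]] - t0
  list(geno = geno, pheno = pheno, qc_report = qc$report,
       manifest = manifest)
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  path
}

#' Run the discovery pipeline
#'
#' QC, covariate residualization, candidate filtering (main-effect scan
#' and/or knowledge filter), exhaustive cross-validated QMDR search,
#' pooled permutation null, significance table, and -- for models passing
#' the corrected-p threshold -- the explicit test of epistasis and the
#' variance-explained comparison. All artifacts are written under
#' `config$out_dir`; a JSON manifest (including a partial one on stage
#' failure) records stage counts, seeds and outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(mode = "discovery", seed = config$seed,
                   config = config[setdiff(names(config), "qc")],
                   qc_thresholds = unclass(config$qc),
                   stages = list(), wall = list(), outputs = character())
  on_fail <- function(stage, e) {
    manifest$error <<- paste0("stage '", stage, "': ", conditionMessage(e))
    write_manifest(manifest, config$out_dir)
    stop("pipeline aborted at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  prep <- tryCatch(pipeline_prepare(config, manifest),
                   error = function(e) on_fail("prepare", e))
  manifest <- prep$manifest
  geno <- prep$geno; pheno <- prep$pheno
  trait <- pheno$residual_trait
  write_qc_report(prep$qc_report, file.path(config$out_dir,
                                            "qc_report.tsv"))

  t0 <- proc.time()[["elapsed"]]
  cand <- tryCatch(
    pipeline_candidates(config, geno, trait),
    error = function(e) on_fail("filter", e))
  manifest$stages$filter <- list(mode = config$filter_mode,
                                 candidate_snps = cand$n_snps,
                                 candidate_pairs = cand$n_pairs)
  manifest$wall$filter <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  plan <- make_fold_plan(length(geno$samples), config$folds,
                         seed = child_seed(config$seed, 101L))
  search <- tryCatch(
    exhaustive_search(geno, trait, plan,
                      candidate_snps = cand$snps, pairs = cand$pairs,
                      top_k = config$top_k, rank_by = config$rank_by,
                      empty_cell_policy = config$empty_cell_policy),
    error = function(e) on_fail("search", e))
  manifest$stages$search <- list(pairs_evaluated = search$n_pairs_evaluated,
                                 models_retained = nrow(search$models))
  manifest$wall$search <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  null <- tryCatch(
    build_null(geno, trait, plan, candidate_snps = cand$snps,
               pairs = cand$pairs, n_perm = config$n_perm,
               top_k = config$top_k,
               seed = child_seed(config$seed, 102L),
               rank_by = config$rank_by,
               empty_cell_policy = config$empty_cell_policy),
    error = function(e) on_fail("permutation", e))
  write_null(null, file.path(config$out_dir, "null_distribution.tsv"))
  sig <- significance_table(search, null)
  data.table::fwrite(sig, file.path(config$out_dir,
                                    "significance_table.tsv"),
                     sep = "\t", quote = FALSE)
  manifest$stages$significance <- list(n_perm = null$n_perm,
                                       pooled = length(null$statistics))
  manifest$wall$permutation <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  hits <- sig[!is.na(sig$p_bonferroni) &
                sig$p_bonferroni < config$carry_bonferroni_max, ,
              drop = FALSE]
  epi <- NULL
  if (nrow(hits)) {
    epi <- tryCatch(
      pipeline_epistasis_stage(config, geno, trait, hits),
      error = function(e) on_fail("epistasis", e))
    data.table::fwrite(epi$table,
                       file.path(config$out_dir, "explicit_epistasis.tsv"),
                       sep = "\t", quote = FALSE)
    vc <- epi$variance
    data.table::fwrite(
      data.frame(adj_r2_reduced = vc$adj_r2_reduced,
                 adj_r2_full = vc$adj_r2_full,
                 percent_increase = vc$percent_increase,
                 lrt_chisq = vc$lrt_chisq, lrt_df = vc$lrt_df,
                 lrt_p = vc$lrt_p, n = vc$n),
      file.path(config$out_dir, "variance_comparison.tsv"),
      sep = "\t", quote = FALSE)
  }
  manifest$stages$epistasis <- list(models_carried = nrow(hits))
  manifest$wall$epistasis <- proc.time()[["elapsed"]] - t0

  manifest$outputs <- list.files(config$out_dir)
  write_manifest(manifest, config$out_dir)
  invisible(manifest)
}

# candidate-set construction per filter mode; returns either a SNP list
# (main-effect route: all pairs searched) or an explicit pair matrix
pipeline_candidates <- function(config, geno, trait) {
  snps <- NULL; pairs <- NULL
  if (config$filter_mode %in% c("main_effect", "both")) {
    scan <- main_effect_scan(geno, trait)
    snps <- main_effect_filter(scan, config$main_effect_cutoff)
    if (config$filter_mode == "main_effect" && length(snps) < 2)
      stop("empty result: fewer than 2 SNPs pass the main-effect filter",
           call. = FALSE)
  }
  if (config$filter_mode %in% c("knowledge", "both")) {
    models <- read_knowledge_table(config$knowledge_file)
    models <- filter_gene_models(models, config$min_implication_index)
    map <- read_snp_gene_map(config$snp_gene_file, geno)
    kp <- expand_to_snp_models(models, map)
    if (config$filter_mode == "knowledge" && nrow(kp) == 0)
      stop("empty result: no SNP pairs survive the knowledge filter",
           call. = FALSE)
    pairs <- kp
  }
  if (config$filter_mode == "both") {
    # union of the two candidate routes, as an explicit pair list
    me_pairs <- if (length(snps) >= 2) t(utils::combn(sort(snps), 2)) else
      matrix(character(0), 0, 2)
    pairs <- unique(rbind(me_pairs, pairs))
    if (nrow(pairs) == 0)
      stop("empty result: no candidate pairs from either filter",
           call. = FALSE)
    snps <- NULL
  }
  n_pairs <- if (!is.null(pairs)) nrow(pairs) else choose(length(snps), 2)
  list(snps = if (is.null(pairs)) snps else NULL, pairs = pairs,
       n_snps = length(snps %||% unique(c(pairs))), n_pairs = n_pairs)
}

pipeline_epistasis_stage <- function(config, geno, trait, hits) {
  rows <- vector("list", nrow(hits))
  members <- unique(c(hits$snp1, hits$snp2))
  calls <- lapply(members, function(s)
    geno$calls[, match(s, geno$snps$snp_id)])
  names(calls) <- members
  for (i in seq_len(nrow(hits))) {
    r <- explicit_permutation_test(
      trait, calls[[hits$snp1[i]]], calls[[hits$snp2[i]]],
      n_perm = config$epi_n_perm, n_strata = config$epi_n_strata,
      seed = child_seed(config$seed, 200L + i), coding = config$epi_coding)
    rows[[i]] <- data.frame(snp1 = hits$snp1[i], snp2 = hits$snp2[i],
                            observed_f = r$observed_f,
                            explicit_epistasis_p = r$p,
                            stringsAsFactors = FALSE)
  }
  idx_calls <- if (!is.null(config$index_snp))
    geno$calls[, match(config$index_snp, geno$snps$snp_id)] else NULL
  vc <- variance_comparison(trait, idx_calls, calls,
                            Map(c, hits$snp1, hits$snp2))
  list(table = do.call(rbind, rows), variance = vc)
}

#' Run the directed-replication pipeline
#'
#' Evaluates only an externally supplied list of SNP-SNP models (e.g.
#' models discovered in another cohort) in this dataset: the same QC and
#' residualization, then QMDR restricted to the listed pairs, with the
#' permutation null built over the same restricted pair set. Pairs whose
#' SNPs are absent after QC are skipped and named in the manifest.
#'
#' @param config a [pipeline_config()] (its filter settings are ignored).
#' @param model_list two-column character matrix (or data.frame) of SNP
#'   pairs to test.
#' @param alpha per-model permutation p-value threshold reported in the
#'   manifest (default 0.05).
#' @return the manifest, invisibly.
#' @export
run_directed <- function(config, model_list, alpha = 0.05) {
  stopifnot(inherits(config, "pipeline_config"))
  model_list <- as.matrix(model_list)
  stopifnot(ncol(model_list) == 2)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(mode = "directed", seed = config$seed,
                   stages = list(), wall = list(), outputs = character())
  on_fail <- function(stage, e) {
    manifest$error <<- paste0("stage '", stage, "': ", conditionMessage(e))
    write_manifest(manifest, config$out_dir)
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  prep <- tryCatch(pipeline_prepare(config, manifest),
                   error = function(e) on_fail("prepare", e))
  manifest <- prep$manifest
  geno <- prep$geno; trait <- prep$pheno$residual_trait
  present <- model_list[, 1] %in% geno$snps$snp_id &
    model_list[, 2] %in% geno$snps$snp_id
  skipped <- model_list[!present, , drop = FALSE]
  manifest$stages$mapping <- list(
    listed = nrow(model_list), tested = sum(present),
    skipped = apply(skipped, 1, paste, collapse = ","))
  if (!any(present))
    on_fail("mapping", simpleError("no listed pair present after QC"))
  pairs <- model_list[present, , drop = FALSE]
  plan <- make_fold_plan(length(geno$samples), config$folds,
                         seed = child_seed(config$seed, 101L))
  search <- exhaustive_search(geno, trait, plan, pairs = pairs,
                              top_k = nrow(pairs),
                              rank_by = config$rank_by,
                              empty_cell_policy = config$empty_cell_policy)
  null <- build_null(geno, trait, plan, pairs = pairs,
                     n_perm = config$n_perm, top_k = nrow(pairs),
                     seed = child_seed(config$seed, 102L),
                     rank_by = config$rank_by,
                     empty_cell_policy = config$empty_cell_policy)
  sig <- significance_table(search, null, m = nrow(pairs))
  sig$significant <- sig$p <= alpha
  data.table::fwrite(sig, file.path(config$out_dir,
                                    "directed_significance.tsv"),
                     sep = "\t", quote = FALSE)
  manifest$stages$directed <- list(alpha = alpha,
                                   significant = sum(sig$significant))
  manifest$outputs <- list.files(config$out_dir)
  write_manifest(manifest, config$out_dir)
  invisible(manifest)
}
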