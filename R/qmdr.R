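#' Cross-validation fold plan
#'
#' Partitions samples into folds of near-equal size (sizes differ by at
#' most one) by a seeded uniform shuffle followed by round-robin
#' assignment.
#'
#' @param n_samples number of samples.
#' @param folds number of folds (default 10).
#' @param seed RNG seed (required; recorded in the plan).
#' @return a `fold_plan`: list with `fold` (integer labels `1..folds` per
#'   sample), `folds`, `seed`.
#' @export
make_fold_plan <- function(n_samples, folds = 10, seed) {
  stopifnot(n_samples >= folds, folds >= 2)
  ord <- local_seed(seed, sample.int(n_samples))
  fold <- integer(n_samples)
  fold[ord] <- rep_len(seq_len(folds), n_samples)
  structure(list(fold = fold, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' QMDR cell assignment for one SNP pair
#'
#' Labels each of the nine two-locus genotype cells *high* or *low* by
#' comparing the cell's mean trait (over the training subset) with the
#' overall training mean: strictly greater means high. Cells with no
#' training members are labelled *empty*. Individuals missing either
#' genotype are excluded.
#'
#' @param g1,g2 genotype vectors (0/1/2/NA) for the two SNPs.
#' @param trait numeric trait vector.
#' @param subset indices of the training subset (default: all samples).
#' @return a `cell_assignment`: list with `labels` (3x3 character matrix,
#'   rows = `g1` 0..2, cols = `g2` 0..2), `cell_means`, `cell_n`,
#'   `overall_mean`.
#' @export
assign_cells <- function(g1, g2, trait, subset = NULL) {
  stopifnot(length(g1) == length(g2), length(trait) == length(g1))
  idx <- subset %||% seq_along(g1)
  if (!length(idx)) stop("empty training subset", call. = FALSE)
  ok <- idx[!is.na(g1[idx]) & !is.na(g2[idx])]
  if (!length(ok))
    stop("degenerate model: all individuals missing a genotype",
         call. = FALSE)
  cell <- 3L * g1[ok] + g2[ok]           # 0..8
  y <- trait[ok]
  cnt <- vapply(0:8, function(c) sum(cell == c), numeric(1))
  sm <- vapply(0:8, function(c) sum(y[cell == c]), numeric(1))
  means <- ifelse(cnt > 0, sm / cnt, NA_real_)
  overall <- mean(y)
  lab <- ifelse(cnt == 0, "empty",
                ifelse(means > overall, "high", "low"))
  # cell = 3*g1+g2 filled column-major puts g2 on rows; transpose so
  # rows index g1
  dim(lab) <- dim(means) <- c(3L, 3L)
  cnt_m <- matrix(cnt, 3L, 3L)
  lab <- t(lab); means <- t(means); cnt_m <- t(cnt_m)
  dn <- list(g1 = 0:2, g2 = 0:2)
  dimnames(lab) <- dimnames(means) <- dimnames(cnt_m) <- dn
  structure(list(labels = lab, cell_means = means, cell_n = cnt_m,
                 overall_mean = overall),
            class = "cell_assignment")
}

#' QMDR statistic for a cell assignment
#'
#' Pools the members of high cells and of low cells (over `subset`) and
#' returns the pooled-variance two-sample t-statistic, signed high minus
#' low. Members of cells labelled *empty* in the assignment join the low
#' pool when `empty_cell_policy = "low"` (default) or are dropped when
#' `"drop"`.
#'
#' @param assignment a [assign_cells()] result.
#' @param g1,g2,trait as in [assign_cells()].
#' @param subset indices to score on (default all samples).
#' @param empty_cell_policy `"low"` or `"drop"`.
#' @return the t-statistic, or `NA` when undefined (a pooled group with
#'   fewer than two members, or zero pooled variance with unequal means).
#' @export
qmdr_t <- function(assignment, g1, g2, trait, subset = NULL,
                   empty_cell_policy = c("low", "drop")) {
  stopifnot(inherits(assignment, "cell_assignment"))
  empty_cell_policy <- match.arg(empty_cell_policy)
  idx <- subset %||% seq_along(g1)
  ok <- idx[!is.na(g1[idx]) & !is.na(g2[idx])]
  if (!length(ok)) return(NA_real_)
  lab <- assignment$labels[cbind(g1[ok] + 1L, g2[ok] + 1L)]
  if (empty_cell_policy == "low") lab[lab == "empty"] <- "low"
  y1 <- trait[ok][lab == "high"]
  y0 <- trait[ok][lab == "low"]
  pooled_t_r(y1, y0)
}

# reference pooled-t used by the R path; mirrors the C++ guard rules
pooled_t_r <- function(y1, y0) {
  n1 <- length(y1); n0 <- length(y0)
  if (n1 < 2 || n0 < 2) return(NA_real_)
  m1 <- mean(y1); m0 <- mean(y0)
  sp2 <- (sum((y1 - m1)^2) + sum((y0 - m0)^2)) / (n1 + n0 - 2)
  if (sp2 <= 0) return(if (m1 == m0) 0 else NA_real_)
  (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

# shared driver: evaluate a P x 2 index matrix of pairs, return per-fold
# train/test matrices from the compiled core
qmdr_eval <- function(dataset, trait, plan, pair_idx, empty_cell_policy) {
  stopifnot(is_genotype_dataset(dataset), inherits(plan, "fold_plan"),
            length(trait) == length(dataset$samples))
  res <- qmdr_core_cpp(dataset$calls,
                       matrix(as.integer(pair_idx - 1L), ncol = 2),
                       as.numeric(trait),
                       as.integer(plan$fold - 1L), plan$folds,
                       as.integer(empty_cell_policy == "low"))
  res
}

#' Cross-validated QMDR evaluation of one SNP pair
#'
#' For each fold, cells are assigned on the training nine-tenths (the
#' overall mean is computed from training data only), the training
#' statistic is computed there, and the testing statistic is computed on
#' the held-out tenth using the training-derived labels. Undefined fold
#' statistics are recorded as `NA` and excluded from the fold means.
#'
#' @param pair character vector of two SNP IDs.
#' @param dataset a `genotype_dataset`.
#' @param trait numeric trait aligned with `dataset$samples`.
#' @param plan a [make_fold_plan()].
#' @param empty_cell_policy see [qmdr_t()].
#' @return a `qmdr_model`: list with `snp1`, `snp2`, `train_t`, `test_t`
#'   (per-fold vectors), `mean_train_t`, `mean_test_t`, `cvc` (`NA` here;
#'   filled by [exhaustive_search()]), `n_folds_defined`.
#' @export
cross_validate_pair <- function(pair, dataset, trait, plan,
                                empty_cell_policy = c("low", "drop")) {
  empty_cell_policy <- match.arg(empty_cell_policy)
  ci <- match(pair, dataset$snps$snp_id)
  if (anyNA(ci)) stop("unknown SNP ID(s): ",
                      paste(pair[is.na(ci)], collapse = ", "), call. = FALSE)
  ci <- sort(ci)[1:2]
  ids <- dataset$snps$snp_id[ci]
  ids <- sort(ids)
  ci <- match(ids, dataset$snps$snp_id)
  res <- qmdr_eval(dataset, trait, plan, matrix(ci, 1), empty_cell_policy)
  tr <- drop(res$train); te <- drop(res$test)
  new_qmdr_model(ids[1], ids[2], tr, te, NA_integer_)
}

new_qmdr_model <- function(s1, s2, train_t, test_t, cvc) {
  structure(list(snp1 = s1, snp2 = s2, train_t = train_t, test_t = test_t,
                 mean_train_t = mean_or_na(train_t),
                 mean_test_t = mean_or_na(test_t),
                 cvc = cvc,
                 n_folds_defined = sum(!is.na(test_t))),
            class = "qmdr_model")
}

mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)

#' Exhaustive cross-validated QMDR pair search
#'
#' Evaluates every unordered pair of the candidate SNPs (or exactly the
#' supplied pairs) and ranks models by mean testing t-statistic
#' (descending; per-fold maximum available via `rank_by = "max"`), with
#' ties broken by mean training t and then lexicographic pair ID. Models
#' whose statistic is undefined in every fold rank last.
#'
#' @param dataset a `genotype_dataset`.
#' @param trait numeric trait aligned with `dataset$samples`.
#' @param plan a [make_fold_plan()].
#' @param candidate_snps character vector of SNP IDs (all pairs searched),
#'   or `NULL` if `pairs` is given.
#' @param pairs optional two-column character matrix of explicit pairs.
#' @param top_k number of top models to retain (default 100; capped at
#'   the number of pairs).
#' @param rank_by `"mean"` (default) or `"max"` of the per-fold testing
#'   statistics.
#' @param empty_cell_policy see [qmdr_t()].
#' @return a `qmdr_search`: list with `models` (data.frame: `snp1`,
#'   `snp2`, `mean_train_t`, `mean_test_t`, `cvc`, `n_folds_defined`, in
#'   rank order), per-fold matrices `train_folds`/`test_folds` for the
#'   retained models, `n_pairs_evaluated`, and the plan/policy used.
#' @export
exhaustive_search <- function(dataset, trait, plan, candidate_snps = NULL,
                              pairs = NULL, top_k = 100,
                              rank_by = c("mean", "max"),
                              empty_cell_policy = c("low", "drop")) {
  rank_by <- match.arg(rank_by)
  empty_cell_policy <- match.arg(empty_cell_policy)
  if (is.null(pairs)) {
    if (is.null(candidate_snps) || length(candidate_snps) < 2)
      stop("need >= 2 candidate SNPs or an explicit pair list",
           call. = FALSE)
    snps <- sort(unique(candidate_snps))
    miss <- setdiff(snps, dataset$snps$snp_id)
    if (length(miss)) stop("unknown SNP ID(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    cmb <- utils::combn(snps, 2)
    pair_ids <- cbind(cmb[1, ], cmb[2, ])
  } else {
    pair_ids <- cbind(pmin(pairs[, 1], pairs[, 2]),
                      pmax(pairs[, 1], pairs[, 2]))
    pair_ids <- unique(pair_ids)
    pair_ids <- pair_ids[order(pair_ids[, 1], pair_ids[, 2]), ,
                         drop = FALSE]
    miss <- setdiff(c(pair_ids), dataset$snps$snp_id)
    if (length(miss)) stop("unknown SNP ID(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- cbind(match(pair_ids[, 1], dataset$snps$snp_id),
               match(pair_ids[, 2], dataset$snps$snp_id))
  res <- qmdr_eval(dataset, trait, plan, idx, empty_cell_policy)
  tr <- res$train; te <- res$test
  mean_tr <- apply(tr, 1, mean_or_na)
  stat <- if (rank_by == "mean") apply(te, 1, mean_or_na)
    else apply(te, 1, function(x) if (all(is.na(x))) NA_real_
               else max(x, na.rm = TRUE))
  # cross-validation consistency: per fold, the best-training pair
  cvc <- integer(nrow(idx))
  for (f in seq_len(plan$folds)) {
    col <- tr[, f]
    if (all(is.na(col))) next
    best <- which.max(replace(col, is.na(col), -Inf))
    cvc[best] <- cvc[best] + 1L
  }
  key <- replace(stat, is.na(stat), -Inf)
  key2 <- replace(mean_tr, is.na(mean_tr), -Inf)
  ord <- order(-key, -key2, pair_ids[, 1], pair_ids[, 2])
  keep <- utils::head(ord, min(top_k, length(ord)))
  models <- data.frame(snp1 = pair_ids[keep, 1], snp2 = pair_ids[keep, 2],
                       mean_train_t = mean_tr[keep],
                       mean_test_t = apply(te[keep, , drop = FALSE], 1,
                                           mean_or_na),
                       rank_stat = stat[keep],
                       cvc = cvc[keep],
                       n_folds_defined = rowSums(!is.na(
                         te[keep, , drop = FALSE])),
                       stringsAsFactors = FALSE)
  structure(list(models = models,
                 train_folds = tr[keep, , drop = FALSE],
                 test_folds = te[keep, , drop = FALSE],
                 n_pairs_evaluated = nrow(idx),
                 rank_by = rank_by, folds = plan$folds,
                 empty_cell_policy = empty_cell_policy),
            class = "qmdr_search")
}

#' @export
print.qmdr_search <- function(x, ...) {
  cat("QMDR exhaustive search:", x$n_pairs_evaluated, "pairs,",
      x$folds, "folds, ranked by", x$rank_by, "testing t\n")
  print(utils::head(x$models, 10), row.names = FALSE)
  invisible(x)
}

#' Write QMDR search results as TSV
#'
#' @param search a `qmdr_search`.
#' @param path output path.
#' @param snp_gene_map optional named vector `snp_id -> gene` to annotate.
#' @return `path`, invisibly.
#' @export
write_search_results <- function(search, path, snp_gene_map = NULL) {
  df <- search$models
  if (!is.null(snp_gene_map)) {
    df$gene1 <- unname(snp_gene_map[df$snp1])
    df$gene2 <- unname(snp_gene_map[df$snp2])
  }
  fold_df <- as.data.frame(search$test_folds)
  names(fold_df) <- paste0("test_t_fold", seq_len(ncol(fold_df)))
  data.table::fwrite(cbind(df, fold_df), path, sep = "\t", quote = FALSE)
  invisible(path)
}
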