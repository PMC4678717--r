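#' Pooled permutation null distribution for the QMDR search
#'
#' For each permutation the trait vector is shuffled against the (fixed)
#' genotype matrix, the exhaustive search is re-run with the same fold
#' plan, and the `top_k` ranking statistics are appended to a single
#' pooled null vector of length `n_perm * top_k`. Permutations are seeded
#' per index, so the result is independent of execution order and
#' reproducible for a given base seed.
#'
#' @param dataset a `genotype_dataset`.
#' @param trait numeric trait aligned with `dataset$samples`.
#' @param plan a [make_fold_plan()].
#' @param candidate_snps,pairs candidate specification as in
#'   [exhaustive_search()].
#' @param n_perm number of permutations (default 1000).
#' @param top_k best models pooled per permutation (default 100).
#' @param seed base RNG seed for the permutation streams.
#' @param rank_by,empty_cell_policy passed to [exhaustive_search()].
#' @return a `null_distribution`: list with `statistics` (numeric vector,
#'   undefined entries removed), `n_perm`, `top_k`, `seed`,
#'   `n_undefined`.
#' @export
build_null <- function(dataset, trait, plan, candidate_snps = NULL,
                       pairs = NULL, n_perm = 1000, top_k = 100, seed,
                       rank_by = c("mean", "max"),
                       empty_cell_policy = c("low", "drop")) {
  stopifnot(n_perm >= 1)
  rank_by <- match.arg(rank_by)
  empty_cell_policy <- match.arg(empty_cell_policy)
  n <- length(trait)
  stats_list <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    perm <- local_seed(child_seed(seed, i), sample.int(n))
    s <- exhaustive_search(dataset, trait[perm], plan,
                           candidate_snps = candidate_snps, pairs = pairs,
                           top_k = top_k, rank_by = rank_by,
                           empty_cell_policy = empty_cell_policy)
    stats_list[[i]] <- s$models$rank_stat
  }
  pooled <- unlist(stats_list, use.names = FALSE)
  n_undef <- sum(is.na(pooled) | pooled == -Inf)
  structure(list(statistics = pooled[!is.na(pooled) & pooled > -Inf],
                 n_perm = as.integer(n_perm), top_k = as.integer(top_k),
                 seed = as.integer(seed), n_undefined = n_undef),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Permutation null:", x$n_perm, "permutations x top", x$top_k,
      "models =", length(x$statistics), "pooled statistics")
  if (x$n_undefined) cat(" (", x$n_undefined, " undefined dropped)",
                         sep = "")
  cat("\n  quantiles:\n")
  print(stats::quantile(x$statistics, c(.5, .9, .95, .99, 1)))
  invisible(x)
}

#' Empirical p-value against a pooled permutation null
#'
#' Uses the add-one rule `p = (1 + #(null >= observed)) / (1 + N)`, which
#' is never zero; the raw proportion `#(null >= observed) / N` is
#' attached as attribute `"raw"`.
#'
#' @param observed observed statistic (`-Inf`/`NA` gives p = 1).
#' @param null a [build_null()] result (or bare numeric vector).
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null) {
  stats <- if (inherits(null, "null_distribution")) null$statistics
    else as.numeric(null)
  if (!length(stats)) stop("empty null distribution", call. = FALSE)
  if (is.na(observed)) observed <- -Inf
  hits <- sum(stats >= observed)
  structure((1 + hits) / (1 + length(stats)), raw = hits / length(stats))
}

#' Bonferroni correction
#'
#' @param p p-value(s).
#' @param m number of tests (default 100, the number of retained models).
#' @return `min(1, p * m)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m = 100) {
  stopifnot(m >= 1)
  pmin(1, as.numeric(p) * m)
}

#' Significance table for a QMDR search
#'
#' @param search a [exhaustive_search()] result.
#' @param null a [build_null()] result.
#' @param m Bonferroni multiplier (default: the null's `top_k`).
#' @return data.frame: `snp1`, `snp2`, `stat`, `raw_p`, `p` (add-one),
#'   `p_bonferroni`, `cvc`.
#' @export
significance_table <- function(search, null, m = NULL) {
  stopifnot(inherits(search, "qmdr_search"),
            inherits(null, "null_distribution"))
  m <- m %||% null$top_k
  ps <- lapply(search$models$rank_stat, empirical_pvalue, null = null)
  data.frame(snp1 = search$models$snp1, snp2 = search$models$snp2,
             stat = search$models$rank_stat,
             raw_p = vapply(ps, attr, numeric(1), "raw"),
             p = vapply(ps, as.numeric, numeric(1)),
             p_bonferroni = bonferroni(vapply(ps, as.numeric, numeric(1)),
                                       m),
             cvc = search$models$cvc,
             stringsAsFactors = FALSE)
}

#' Persist / load a null distribution as TSV
#'
#' Single-column TSV with `#` metadata header lines recording `n_perm`,
#' `top_k` and `seed`.
#'
#' @param null a `null_distribution`.
#' @param path file path.
#' @return `path` (writer) or the `null_distribution` (reader).
#' @export
write_null <- function(null, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_perm=%d", null$n_perm),
               sprintf("# top_k=%d", null$top_k),
               sprintf("# seed=%d", null$seed),
               sprintf("# n_undefined=%d", null$n_undefined),
               "statistic",
               format(null$statistics, digits = 17, trim = TRUE,
                      scientific = FALSE)), con)
  invisible(path)
}

#' @rdname write_null
#' @export
read_null <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    as.integer(sub(".*=", "", hit[1]))
  }
  body <- lines[!startsWith(lines, "#")][-1]  # drop header row
  structure(list(statistics = as.numeric(body),
                 n_perm = get_meta("n_perm"), top_k = get_meta("top_k"),
                 seed = get_meta("seed"),
                 n_undefined = get_meta("n_undefined")),
            class = "null_distribution")
}
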