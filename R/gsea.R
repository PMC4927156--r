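#' @title Gene set enrichment over functional categories
#' @description Rank-based enrichment of one condition's fitness scores
#'   over gene sets (e.g. COG functional categories, single-letter codes
#'   such as J = translation, L = replication/repair): a weighted
#'   Kolmogorov-Smirnov running sum with set-membership permutation
#'   p-values. Because a single condition's score vector is the input,
#'   the null permutes gene labels (set membership at fixed set size),
#'   not samples.
#' @name enrichment
NULL

#' GSEA enrichment score
#'
#' Genes are ranked by decreasing score; walking down the ranking, hits
#' (set members) add `|score|^p` normalized by the sum over hits, misses
#' subtract `1/(N - N_hits)`. The enrichment score is the running sum's
#' maximum deviation from zero, signed. `p = 0` gives the classic KS
#' statistic (rank-only); the default `p = 1` weights by score magnitude.
#'
#' @param scores Named numeric vector of fitness scores (names = genes).
#' @param gene_set Character vector of set members.
#' @param p Weighting exponent (default 1).
#' @return The enrichment score in \[-1, 1\].
#' @export
gsea_es <- function(scores, gene_set, p = 1) {
  if (is.null(names(scores))) stop("scores must be a named vector")
  scores <- scores[is.finite(scores)]
  genes <- names(scores)
  hits <- genes %in% gene_set
  if (!any(hits)) stop("gene set does not intersect the ranked genes")
  if (all(hits)) stop("gene set equals the ranked universe (degenerate)")
  ord <- order(scores, decreasing = TRUE)
  hits <- hits[ord]
  w <- abs(scores[ord])^p
  inc <- ifelse(hits, w / sum(w[hits]), 0)
  dec <- ifelse(hits, 0, 1 / sum(!hits))
  run <- cumsum(inc - dec)
  unname(run[which.max(abs(run))])
}

#' GSEA permutation p-value
#'
#' Null: gene sets of the same size drawn uniformly from the ranked
#' universe (set-membership permutation). Two-sided:
#' `p = (1 + #(|ES_null| >= |ES_obs|)) / (n_perm + 1)`, so p is never 0
#' and has resolution `1/(n_perm + 1)`. When the number of distinct sets
#' `choose(N, k)` is at most `n_perm` the null is enumerated exhaustively
#' instead and `p` is the exact tail fraction.
#'
#' @param scores Named numeric vector of fitness scores.
#' @param gene_set Character vector of set members.
#' @param p Weighting exponent (default 1).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return A list of class `enrichment_result`: `es`, `p_value`, `n_perm`
#'   (or the enumeration size), `exact` (logical), `set_size`, `seed`.
#' @export
gsea_pvalue <- function(scores, gene_set, p = 1, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  scores <- scores[is.finite(scores)]
  genes <- names(scores)
  set_in <- intersect(gene_set, genes)
  k <- length(set_in)
  es_obs <- gsea_es(scores, gene_set, p = p)

  n_sets <- suppressWarnings(choose(length(genes), k))
  if (is.finite(n_sets) && n_sets <= n_perm) {
    combs <- utils::combn(genes, k)
    es_null <- apply(combs, 2, function(s) gsea_es(scores, s, p = p))
    p_value <- mean(abs(es_null) >= abs(es_obs) - 1e-12)
    exact <- TRUE
    n_used <- ncol(combs)
  } else {
    rng <- local_rng(seed)
    on.exit(restore_rng(rng))
    es_null <- vapply(seq_len(n_perm), function(i) {
      gsea_es(scores, sample(genes, k), p = p)
    }, numeric(1))
    p_value <- (1 + sum(abs(es_null) >= abs(es_obs) - 1e-12)) / (n_perm + 1)
    exact <- FALSE
    n_used <- n_perm
  }
  structure(list(es = es_obs, p_value = p_value, n_perm = n_used,
                 exact = exact, set_size = k, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: ES = %.3f, p = %.4g (%s, n = %d, set size %d)\n",
              x$es, x$p_value, if (x$exact) "exact" else "permutation",
              x$n_perm, x$set_size))
  invisible(x)
}

#' Read a gene-set mapping file
#'
#' Delimited text with two columns, gene and category; genes may appear
#' under several categories (multi-category genes count in each).
#'
#' @param path File path.
#' @return Named list of character vectors (category -> genes).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  sep <- guess_sep(lines[[1]])
  raw <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("gene set file needs gene and category columns")
  split(as.character(raw[[1]]), as.character(raw[[2]]))
}

#' Enrichment of every category for one condition
#'
#' Convenience wrapper running [gsea_pvalue()] for each gene set against a
#' condition's score profile.
#'
#' @param m A `screen_matrix` at stage `"score"`.
#' @param condition Condition label (column) to analyze.
#' @param sets Named list of gene sets (see [read_gene_sets()]).
#' @param ... Passed to [gsea_pvalue()].
#' @return Data.frame with one row per category: `category`, `es`,
#'   `p_value`, `set_size`.
#' @export
gsea_condition <- function(m, condition, sets, ...) {
  j <- match(condition, m$conditions$label)
  if (is.na(j)) stop("unknown condition: ", condition)
  x <- m$values[, j]
  x[!m$mask[, j]] <- NA_real_
  names(x) <- genes_of(m)
  rows <- lapply(names(sets), function(cat) {
    res <- tryCatch(gsea_pvalue(x, sets[[cat]], ...),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(category = cat, es = res$es, p_value = res$p_value,
               set_size = res$set_size, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
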