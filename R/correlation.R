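#' @title Gene-gene correlation networks
#' @description Pairwise Pearson correlations between gene fitness-score
#'   profiles, permutation-based FDR significance cutoffs, a
#'   Bonferroni-style t-test threshold, average-linkage hierarchical
#'   clustering with Cluster 3.0 compatible output, and the
#'   condition-sampling experiment relating dataset size to significance
#'   cutoffs.
#' @name correlation_network
NULL

#' Pairwise gene-gene Pearson correlations
#'
#' Correlations are computed over the conditions where both genes have
#' reliable scores (pairwise-complete). Pairs with fewer shared conditions
#' than `min_overlap` are omitted (small overlaps produce spuriously high
#' |r|); the default overlap requirement, 75% of conditions, matches the
#' reliability filter upstream. Zero-variance profiles give an undefined
#' correlation (`NA`), reported but excluded from cutoff computations.
#'
#' @param m A `screen_matrix` at stage `"score"`.
#' @param min_overlap Minimum shared conditions per pair (>= 3);
#'   default `ceiling(0.75 * n_conditions)`.
#' @return A list of class `correlation_set`: `pairs` (data.frame `gene1`,
#'   `gene2`, `r`, `n_overlap`, unordered pairs with `gene1` index <
#'   `gene2` index), `n_genes`, `n_conditions`, `n_omitted` (pairs dropped
#'   for insufficient overlap).
#' @export
pairwise_correlations <- function(m, min_overlap = NULL) {
  stopifnot(inherits(m, "screen_matrix"))
  if (is.null(min_overlap)) min_overlap <- ceiling(0.75 * ncol(m$values))
  if (min_overlap < 3L) stop("min_overlap must be >= 3")
  V <- m$values
  V[!m$mask] <- NA_real_
  R <- suppressWarnings(stats::cor(t(V), use = "pairwise.complete.obs"))
  overlap <- tcrossprod(m$mask * 1L)
  g <- genes_of(m)
  ut <- upper.tri(R)
  idx <- which(ut, arr.ind = TRUE)
  r <- R[ut]
  n_ov <- overlap[ut]
  keep <- n_ov >= min_overlap
  pairs <- data.frame(
    gene1 = g[idx[keep, 1]], gene2 = g[idx[keep, 2]],
    r = r[keep], n_overlap = n_ov[keep], stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, n_genes = length(g),
                 n_conditions = ncol(V), n_omitted = sum(!keep),
                 min_overlap = min_overlap),
            class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf(
    "correlation_set: %d genes, %d conditions; %d pairs (%d omitted, overlap < %d)\n",
    x$n_genes, x$n_conditions, nrow(x$pairs), x$n_omitted, x$min_overlap))
  r <- x$pairs$r[is.finite(x$pairs$r)]
  if (length(r))
    cat(sprintf("  r: median %.3f, IQR %.3f\n", stats::median(r),
                stats::IQR(r)))
  invisible(x)
}

# Permute each gene's reliable values across its own unmasked positions,
# preserving the mask pattern and each gene's marginal distribution.
permute_profiles <- function(V, mask) {
  for (i in seq_len(nrow(V))) {
    j <- which(mask[i, ])
    if (length(j) > 1L) V[i, j] <- V[i, sample(j)]
  }
  V
}

#' Permutation-FDR cutoff for gene-pair correlations
#'
#' The null model destroys shared condition structure while keeping each
#' gene's marginal score distribution: each gene's profile is permuted
#' independently across its unmasked conditions, and the pairwise
#' correlations recomputed. For cutoff `c` the FDR estimate is the mean
#' null count of pairs with |r| >= c divided by the observed count;
#' the reported cutoff is the smallest `c` on a 0.01 grid with estimated
#' FDR <= `alpha`. Two-sided in |r|; deterministic given `seed`.
#'
#' @param m A `screen_matrix` at stage `"score"`.
#' @param alpha Target FDR (0.05).
#' @param n_perm Number of profile permutations (>= 20).
#' @param seed Integer seed.
#' @param min_overlap As in [pairwise_correlations()].
#' @param grid_step Cutoff grid step (0.01).
#' @param return_null Also return the pooled null |r| values (for
#'   diagnostics and independent re-evaluation of the FDR curve).
#' @return A list of class `correlation_cutoff`: `cutoff`, `fdr`
#'   (achieved), `alpha`, `n_perm`, `n_pairs`, `grid` (data.frame `c`,
#'   `observed`, `null_mean`, `fdr`), and optionally `null_abs_r`. When no
#'   pair is observed at any cutoff the `cutoff` is `NA` with a
#'   "no significant correlations" message.
#' @export
correlation_fdr_cutoff <- function(m, alpha = 0.05, n_perm = 50L,
                                   seed = 1L, min_overlap = NULL,
                                   grid_step = 0.01, return_null = FALSE) {
  if (n_perm < 20L) stop("n_perm must be >= 20")
  obs <- pairwise_correlations(m, min_overlap = min_overlap)
  r_obs <- abs(obs$pairs$r)
  r_obs <- r_obs[is.finite(r_obs)]

  V <- m$values
  V[!m$mask] <- NA_real_
  mo <- obs$min_overlap

  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  null_abs <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    Vp <- permute_profiles(V, m$mask)
    Rp <- suppressWarnings(stats::cor(t(Vp), use = "pairwise.complete.obs"))
    overlap <- tcrossprod(m$mask * 1L)
    ut <- upper.tri(Rp)
    rp <- abs(Rp[ut])
    keep <- overlap[ut] >= mo & is.finite(rp)
    null_abs[[p]] <- rp[keep]
  }
  null_all <- unlist(null_abs)

  grid <- seq(grid_step, 1, by = grid_step)
  xs <- sort(r_obs)
  ns <- sort(null_all)
  observed <- length(xs) - findInterval(grid - 1e-12, xs)
  null_mean <- (length(ns) - findInterval(grid - 1e-12, ns)) / n_perm
  fdr <- ifelse(observed > 0, pmin(1, null_mean / observed), NA_real_)

  if (all(observed == 0)) {
    message("no significant correlations: no observed pairs at any cutoff")
    cutoff <- NA_real_
    achieved <- NA_real_
  } else {
    ok <- which(!is.na(fdr) & fdr <= alpha)
    if (length(ok) == 0L) {
      warning("no cutoff achieves FDR <= ", alpha)
      cutoff <- NA_real_
      achieved <- NA_real_
    } else {
      cutoff <- grid[ok[1]]
      achieved <- fdr[ok[1]]
    }
  }
  out <- list(cutoff = cutoff, fdr = achieved, alpha = alpha,
              n_perm = n_perm, n_pairs = length(r_obs),
              grid = data.frame(c = grid, observed = observed,
                                null_mean = null_mean, fdr = fdr))
  if (return_null) out$null_abs_r <- null_all
  structure(out, class = "correlation_cutoff")
}

#' @export
print.correlation_cutoff <- function(x, ...) {
  cat(sprintf(
    "correlation_cutoff: |r| >= %s (target FDR %.2f, achieved %s; %d pairs, %d permutations)\n",
    format(x$cutoff), x$alpha, format(signif(x$fdr, 3)), x$n_pairs, x$n_perm))
  invisible(x)
}

#' Bonferroni-corrected correlation threshold
#'
#' The |r| at which the two-sided t-test for a Pearson correlation over
#' `n_conditions` observations (`t = r sqrt((n-2)/(1-r^2))`, `df = n-2`)
#' has p-value `alpha / n_pairs`. Closed form via the t quantile:
#' `r* = t* / sqrt(n - 2 + t*^2)`.
#'
#' @param n_conditions Number of conditions (>= 4).
#' @param n_pairs Number of gene pairs tested.
#' @param alpha Family-wise error target (0.05).
#' @return The correlation threshold in \[0, 1\]; 1 (with a warning) when
#'   the corrected level is unattainable.
#' @export
bonferroni_cutoff <- function(n_conditions, n_pairs, alpha = 0.05) {
  if (n_conditions < 4L) stop("n_conditions must be >= 4")
  p_target <- alpha / n_pairs
  if (p_target >= 1) return(0)
  tstar <- stats::qt(1 - p_target / 2, df = n_conditions - 2)
  if (!is.finite(tstar)) {
    warning("corrected level unattainable; returning 1")
    return(1)
  }
  rstar <- tstar / sqrt(n_conditions - 2 + tstar^2)
  if (rstar >= 1) {
    warning("corrected level unattainable; returning 1")
    return(1)
  }
  rstar
}

#' Average-linkage hierarchical clustering of a score matrix
#'
#' Distance `1 - Pearson r` (pairwise-complete) and average linkage, for
#' both genes and conditions — the organization used for screen heatmaps.
#' The matrix should have passed [filter_low_coverage()] so overlaps are
#' adequate; undefined correlations (zero-variance profiles) are treated
#' as distance 1 with a warning.
#'
#' @param m A `screen_matrix` at stage `"score"` with >= 2 genes.
#' @return A list of class `screen_clust`: `genes` and `conditions`
#'   (each an [stats::hclust] tree), plus the matrix `m`.
#' @seealso [write_cluster3()] for Cluster 3.0 compatible output files.
#' @export
hierarchical_cluster <- function(m) {
  stopifnot(inherits(m, "screen_matrix"))
  if (nrow(m$values) < 2L) stop("need >= 2 genes to cluster")
  V <- m$values
  V[!m$mask] <- NA_real_
  cor_dist <- function(X) {
    R <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
    if (any(!is.finite(R))) {
      warning("undefined correlations treated as distance 1")
      R[!is.finite(R)] <- 0
    }
    stats::as.dist(1 - R)
  }
  gh <- stats::hclust(cor_dist(V), method = "average")
  ch <- if (ncol(V) >= 2L) stats::hclust(cor_dist(t(V)), method = "average")
        else NULL
  structure(list(genes = gh, conditions = ch, m = m),
            class = "screen_clust")
}

#' @export
print.screen_clust <- function(x, ...) {
  cat(sprintf("screen_clust: %d genes x %d conditions, average linkage on 1 - r\n",
              nrow(x$m$values), ncol(x$m$values)))
  invisible(x)
}

# One tree in Cluster 3.0 .gtr/.atr format: NODE rows joining item or node
# ids with "correlation" = 1 - merge height.
write_tree_file <- function(h, ids, node_prefix, path) {
  n <- length(ids)
  lines <- character(nrow(h$merge))
  node_id <- function(k) sprintf("NODE%dX", k)
  ref <- function(v) if (v < 0) ids[-v] else node_id(v)
  for (k in seq_len(nrow(h$merge))) {
    lines[k] <- paste(node_id(k), ref(h$merge[k, 1]), ref(h$merge[k, 2]),
                      format(1 - h$height[k], digits = 10), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write Cluster 3.0 compatible clustered output
#'
#' Emits `<prefix>.cdt` (the clustered data table, rows and columns in
#' dendrogram order with GID/AID identifiers), `<prefix>.gtr` (gene tree)
#' and `<prefix>.atr` (condition tree), readable by Java TreeView and
#' compatible consumers.
#'
#' @param cl A `screen_clust` from [hierarchical_cluster()].
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_cluster3 <- function(cl, prefix) {
  m <- cl$m
  V <- m$values
  V[!m$mask] <- NA_real_
  g <- genes_of(m)
  cond <- m$conditions$label
  go <- cl$genes$order
  co <- if (!is.null(cl$conditions)) cl$conditions$order else seq_along(cond)

  gids <- sprintf("GENE%dX", seq_along(g))
  aids <- sprintf("ARRY%dX", seq_along(cond))

  files <- character(0)
  gtr <- paste0(prefix, ".gtr")
  write_tree_file(cl$genes, gids, "NODE", gtr)
  files <- c(files, gtr)
  if (!is.null(cl$conditions)) {
    atr <- paste0(prefix, ".atr")
    write_tree_file(cl$conditions, aids, "NODE", atr)
    files <- c(files, atr)
  }

  cdt <- paste0(prefix, ".cdt")
  con <- file(cdt, "w")
  writeLines(paste(c("GID", "UNIQID", "NAME", "GWEIGHT", cond[co]),
                   collapse = "\t"), con)
  writeLines(paste(c("AID", "", "", "", aids[co]), collapse = "\t"), con)
  writeLines(paste(c("EWEIGHT", "", "", "", rep("1", length(co))),
                   collapse = "\t"), con)
  for (i in go) {
    vals <- ifelse(is.na(V[i, co]), "", format(V[i, co], digits = 10))
    writeLines(paste(c(gids[i], g[i], g[i], "1", vals), collapse = "\t"), con)
  }
  close(con)
  files <- c(files, cdt)
  invisible(files)
}

#' Condition-sampling curve
#'
#' Quantifies how the number of screened conditions shapes the gene-pair
#' correlation distribution and its significance cutoffs: for each N in
#' `Ns`, sample N conditions without replacement `n_repeats` times and
#' record the IQR of the pair-correlation distribution, the
#' permutation-FDR cutoff, and the Bonferroni threshold; report the means.
#' Fewer conditions widen the correlation distribution and push both
#' cutoffs up.
#'
#' @param m A `screen_matrix` at stage `"score"`.
#' @param Ns Integer vector of condition counts; entries < 4 are skipped
#'   with a warning, entries above `ncol(m)` are an error.
#' @param n_repeats Independent samplings per N (4).
#' @param seed Integer seed (drives both the sampling and the permutation
#'   cutoffs).
#' @param alpha Target FDR (0.05).
#' @param n_perm Permutations per cutoff (20).
#' @param min_overlap_frac Pair-overlap requirement as a fraction of the
#'   sampled N (0.75).
#' @return A data.frame of class `sampling_curve`: `n_conditions`,
#'   `mean_iqr`, `mean_fdr_cutoff`, `mean_bonferroni_cutoff`, `n_repeats`.
#' @export
condition_sampling_curve <- function(m, Ns, n_repeats = 4L, seed = 1L,
                                     alpha = 0.05, n_perm = 20L,
                                     min_overlap_frac = 0.75) {
  stopifnot(inherits(m, "screen_matrix"))
  n_cond <- ncol(m$values)
  if (any(Ns > n_cond)) stop("Ns may not exceed the number of conditions")
  skip <- Ns < 4L
  if (any(skip)) {
    warning("skipping N < 4: ", paste(Ns[skip], collapse = ", "))
    Ns <- Ns[!skip]
  }
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))

  rows <- lapply(Ns, function(N) {
    iqr <- fdrc <- bonf <- numeric(n_repeats)
    for (rep_i in seq_len(n_repeats)) {
      j <- sample.int(n_cond, N)
      ms <- m[, j]
      mo <- max(3L, ceiling(min_overlap_frac * N))
      ps <- pairwise_correlations(ms, min_overlap = mo)
      r <- ps$pairs$r[is.finite(ps$pairs$r)]
      iqr[rep_i] <- stats::IQR(r)
      # derive a sub-seed so cutoffs are reproducible but distinct
      sub_seed <- (seed + 7919L * N + rep_i) %% .Machine$integer.max
      cf <- correlation_fdr_cutoff(ms, alpha = alpha, n_perm = n_perm,
                                   seed = sub_seed, min_overlap = mo)
      fdrc[rep_i] <- cf$cutoff
      bonf[rep_i] <- bonferroni_cutoff(N, length(r), alpha)
    }
    data.frame(n_conditions = N, mean_iqr = mean(iqr),
               mean_fdr_cutoff = mean(fdrc, na.rm = TRUE),
               mean_bonferroni_cutoff = mean(bonf),
               n_repeats = n_repeats)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sampling_curve", "data.frame")
  out
}
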