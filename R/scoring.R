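#' @title Fitness scores and FDR-controlled phenotype calls
#' @description Gene x condition fitness scores are regularized
#'   Welch-style statistics comparing a gene's normalized measurements in
#'   one condition against its own measurements across the other
#'   conditions of the same batch. Negative scores denote sensitivity,
#'   positive scores resistance. Per-condition cutoffs are then set so the
#'   empirical false-discovery rate against a robust Gaussian null is at
#'   most alpha, independently per tail, which allows the asymmetric
#'   cutoffs observed in practice.
#' @name scoring
NULL

condition_id <- function(conditions) {
  format_condition_label(conditions$name, conditions$concentration,
                         conditions$batch)
}

#' Compute fitness scores
#'
#' For gene g in condition c the score is
#' \deqn{S = (\mu_t - \mu_r) / \sqrt{\max(s_t^2, s^2_{min})/n_t + s_r^2/n_r}}
#' where \eqn{\mu_t, s_t^2} are the mean and variance of the gene's
#' normalized values over the treated replicates, \eqn{\mu_r, s_r^2} over
#' the reference set (the same gene's measurements across all other
#' conditions in the batch, or an explicit control condition), and
#' \eqn{s^2_{min}} is the median per-gene treated variance within the
#' condition — a variance floor that prevents tiny-variance artifacts at
#' 2-3 replicates. With a single treated replicate the floor supplies the
#' variance.
#'
#' @param m A `screen_matrix` at stage `"normalized"` with one column per
#'   plate (condition replicate).
#' @param reference `"batch_others"` (default): reference a gene by its own
#'   measurements across the other conditions of the batch.
#'   `"control"`: use the batch's conditions flagged `is_control`.
#' @param var_floor Apply the median-variance floor (default TRUE). The
#'   unfloored statistic is exactly antisymmetric under exchanging the
#'   treated and reference sets.
#' @param min_reference Minimum reference measurements per gene (2); genes
#'   with fewer get a masked score.
#' @return A `screen_matrix` with stage `"score"`, one column per
#'   condition.
#' @export
fitness_scores <- function(m, reference = c("batch_others", "control"),
                           var_floor = TRUE, min_reference = 2L) {
  stopifnot(inherits(m, "screen_matrix"))
  reference <- match.arg(reference)
  V <- m$values
  V[!m$mask] <- NA_real_
  cid <- condition_id(m$conditions)
  batch <- m$conditions$batch

  cond_first <- !duplicated(cid)
  out_cid <- cid[cond_first]
  out_cond <- m$conditions[cond_first, , drop = FALSE]
  out_cond$replicate <- 1L
  out_cond$label <- out_cid
  if (reference == "control") {
    is_ctrl_cond <- m$conditions$is_control[cond_first]
    out_cid <- out_cid[!is_ctrl_cond]
    out_cond <- out_cond[!is_ctrl_cond, , drop = FALSE]
  }

  scores <- matrix(NA_real_, nrow = nrow(V), ncol = length(out_cid),
                   dimnames = list(rownames(V), out_cid))

  for (k in seq_along(out_cid)) {
    c_this <- out_cid[k]
    b <- out_cond$batch[k]
    jt <- cid == c_this
    jr <- if (reference == "batch_others") {
      batch == b & cid != c_this
    } else {
      batch == b & m$conditions$is_control & cid != c_this
    }
    if (!any(jr)) next

    Vt <- V[, jt, drop = FALSE]
    Vr <- V[, jr, drop = FALSE]
    n_t <- rowSums(!is.na(Vt))
    n_r <- rowSums(!is.na(Vr))
    mu_t <- rowMeans(Vt, na.rm = TRUE)
    mu_r <- rowMeans(Vr, na.rm = TRUE)
    ss_t <- rowSums(Vt^2, na.rm = TRUE)
    ss_r <- rowSums(Vr^2, na.rm = TRUE)
    var_t <- ifelse(n_t >= 2, (ss_t - n_t * mu_t^2) / (n_t - 1), NA_real_)
    var_r <- ifelse(n_r >= 2, (ss_r - n_r * mu_r^2) / (n_r - 1), NA_real_)
    var_t <- pmax(var_t, 0)  # numerical guard
    var_r <- pmax(var_r, 0)

    if (var_floor) {
      s2min <- stats::median(var_t[n_t >= 2], na.rm = TRUE)
      if (is.na(s2min)) s2min <- 0
      var_t_eff <- pmax(var_t, s2min)
      var_t_eff[is.na(var_t)] <- s2min
    } else {
      var_t_eff <- var_t
    }

    denom <- sqrt(var_t_eff / n_t + var_r / n_r)
    s <- (mu_t - mu_r) / denom
    bad <- n_t < 1L | n_r < min_reference | !is.finite(s)
    s[bad] <- NA_real_
    scores[, k] <- s
  }

  screen_matrix(scores, out_cond, mask = is.finite(scores), stage = "score")
}

# One-tail empirical FDR cutoff search on a 0.01 grid. `tail_count(c)` is
# the number of observed scores at or beyond c; expected counts come from
# the robust Gaussian null.
fdr_tail_cutoff <- function(x, alpha, grid_step, center, scale, tail) {
  xt <- if (tail == "pos") x[x > 0] else -x[x < 0]
  grid_max <- max(abs(x))
  grid <- seq(grid_step, grid_max + grid_step, by = grid_step)
  xs <- sort(xt)
  # observed count at or beyond each grid point
  observed <- length(xs) - findInterval(grid - 1e-12, xs)
  expected <- if (tail == "pos") {
    length(x) * stats::pnorm(grid, center, scale, lower.tail = FALSE)
  } else {
    length(x) * stats::pnorm(-grid, center, scale, lower.tail = TRUE)
  }
  fdr <- ifelse(observed > 0, pmin(1, expected / observed), NA_real_)
  ok <- which(!is.na(fdr) & fdr <= alpha)
  if (length(ok) == 0L) {
    warning(sprintf("no %s-tail cutoff achieves FDR <= %g; cutoff set beyond max |score|",
                    tail, alpha))
    list(cutoff = grid_max + grid_step, fdr = NA_real_)
  } else {
    list(cutoff = grid[ok[1]], fdr = fdr[ok[1]])
  }
}

#' Per-condition empirical FDR score cutoffs
#'
#' Fits a robust Gaussian null `N(median, 1.4826 x MAD)` to each
#' condition's score distribution and, independently per tail, finds the
#' smallest cutoff magnitude `c` (on a grid of step `grid_step`) at which
#' the estimated FDR — expected null scores beyond `c` divided by observed
#' scores beyond `c`, capped at 1 — is at most `alpha`. Tails are treated
#' independently, so negative and positive cutoffs may differ in
#' magnitude. If no grid point qualifies, the cutoff is placed beyond the
#' most extreme score (zero calls) with a warning.
#'
#' @param m A `screen_matrix` at stage `"score"`, or a single numeric
#'   vector of scores for one condition.
#' @param alpha Target FDR in (0, 1); default 0.05.
#' @param grid_step Cutoff search grid step (0.01).
#' @param min_scores Minimum finite scores a condition must have (500);
#'   the empirical tail-count estimate is unstable below that.
#' @return A data.frame of class `condition_cutoffs`: `condition`,
#'   `neg_cutoff` (< 0), `pos_cutoff` (> 0), `alpha`, achieved `fdr_neg`,
#'   `fdr_pos`, `n`, and the null parameters `null_center`, `null_scale`.
#' @export
fdr_cutoffs <- function(m, alpha = 0.05, grid_step = 0.01,
                        min_scores = 500L) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (is.numeric(m)) {
    score_list <- list(scores = m)
  } else {
    stopifnot(inherits(m, "screen_matrix"))
    V <- m$values
    V[!m$mask] <- NA_real_
    score_list <- lapply(seq_len(ncol(V)), function(j) V[, j])
    names(score_list) <- m$conditions$label
  }
  rows <- lapply(names(score_list), function(cond) {
    x <- score_list[[cond]]
    x <- x[is.finite(x)]
    if (length(x) < min_scores)
      stop(sprintf("condition '%s' has %d finite scores (< %d required)",
                   cond, length(x), min_scores))
    center <- stats::median(x)
    scale <- stats::mad(x)
    if (scale == 0) stop(sprintf("condition '%s' has zero MAD", cond))
    neg <- fdr_tail_cutoff(x, alpha, grid_step, center, scale, "neg")
    pos <- fdr_tail_cutoff(x, alpha, grid_step, center, scale, "pos")
    data.frame(condition = cond, neg_cutoff = -neg$cutoff,
               pos_cutoff = pos$cutoff, alpha = alpha,
               fdr_neg = neg$fdr, fdr_pos = pos$fdr, n = length(x),
               null_center = center, null_scale = scale,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("condition_cutoffs", "data.frame")
  out
}

#' Call conditional phenotypes
#'
#' A gene has a conditional phenotype when its score reaches the
#' condition's cutoff: `score <= neg_cutoff` (sensitive) or
#' `score >= pos_cutoff` (resistant); boundaries inclusive. Masked scores
#' are never called.
#'
#' @param m A `screen_matrix` at stage `"score"`.
#' @param cutoffs A `condition_cutoffs` from [fdr_cutoffs()] computed on
#'   the same matrix.
#' @return A data.frame of calls: `gene`, `condition`, `sign`
#'   (`"sensitive"`/`"resistant"`), `score`, `cutoff`.
#' @export
call_phenotypes <- function(m, cutoffs) {
  stopifnot(inherits(m, "screen_matrix"))
  out <- list()
  for (j in seq_len(ncol(m$values))) {
    cond <- m$conditions$label[j]
    ci <- match(cond, cutoffs$condition)
    if (is.na(ci)) stop("no cutoffs for condition: ", cond)
    x <- m$values[, j]
    ok <- m$mask[, j]
    sens <- ok & x <= cutoffs$neg_cutoff[ci]
    res <- ok & x >= cutoffs$pos_cutoff[ci]
    if (any(sens))
      out[[length(out) + 1L]] <- data.frame(
        gene = genes_of(m)[sens], condition = cond, sign = "sensitive",
        score = x[sens], cutoff = cutoffs$neg_cutoff[ci],
        stringsAsFactors = FALSE)
    if (any(res))
      out[[length(out) + 1L]] <- data.frame(
        gene = genes_of(m)[res], condition = cond, sign = "resistant",
        score = x[res], cutoff = cutoffs$pos_cutoff[ci],
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene = character(0), condition = character(0),
                      sign = character(0), score = numeric(0),
                      cutoff = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Responsive genes
#'
#' A responsive gene has at least one conditional phenotype anywhere in
#' the dataset.
#'
#' @param calls Calls from [call_phenotypes()].
#' @return Sorted character vector of gene identifiers.
#' @export
responsive_genes <- function(calls) {
  sort(unique(calls$gene))
}
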