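#' @title Synthetic colony screens with planted ground truth
#' @description Generates arrayed-colony screens under a multiplicative
#'   opacity model: per-gene baseline x planted gene-condition effect x
#'   smooth quartic plate-surface bias x edge multiplier x lognormal noise,
#'   with random colony dropout. The planted truth (effects, surfaces,
#'   dropouts) is returned alongside the data so every downstream stage can
#'   be validated by recovery.
#' @name synthetic_screen
NULL

# Bivariate polynomial basis of total degree <= `degree` on grid
# coordinates scaled to [-1, 1]. Shared by the generator and the surface
# fitter so planted and recovered coefficients are directly comparable.
poly_basis <- function(row, col, n_rows, n_cols, degree = 4L) {
  u <- if (n_rows > 1L) (2 * (row - 1) / (n_rows - 1)) - 1 else rep(0, length(row))
  v <- if (n_cols > 1L) (2 * (col - 1) / (n_cols - 1)) - 1 else rep(0, length(col))
  terms <- list()
  nm <- character(0)
  for (d in 0:degree) {
    for (i in d:0) {
      j <- d - i
      terms[[length(terms) + 1L]] <- u^i * v^j
      nm <- c(nm, sprintf("u%dv%d", i, j))
    }
  }
  m <- do.call(cbind, terms)
  colnames(m) <- nm
  m
}

#' Configure a synthetic screen
#'
#' Builds a reproducible simulation configuration. Everything that is
#' "truth" (per-gene baselines, per-plate surface coefficients, planted
#' effects) is materialized here from `seed`, so that re-running
#' [simulate_screen()] with a different seed changes only the noise and
#' dropout realizations, never the planted structure.
#'
#' Defaults mirror a 1536-format screen: a 32 x 48 grid, lognormal
#' measurement noise with standard deviation 0.15 on log-opacity, 2%
#' colony dropout, an edge-growth multiplier of 1.3 on the outermost two
#' rows/columns, and plate-surface biases whose log-values are scaled to
#' standard deviation `log1p(surface_amplitude)` (so amplitude 0.3 means
#' typical +/-30% multiplicative bias across a plate).
#'
#' @param n_genes Number of mutants; placed row-major on the grid
#'   (`n_genes <= n_rows * n_cols`).
#' @param conditions Condition data.frame from [condition_meta()] (one row
#'   per condition, `replicate` ignored here).
#' @param n_replicates Replicate plates per condition (scalar or one per
#'   condition).
#' @param n_rows,n_cols Grid dimensions.
#' @param surface_amplitude Plate-surface bias amplitude (0 = flat).
#' @param edge_multiplier Multiplier applied to the outermost `edge_width`
#'   rows and columns (> 0; 1 disables).
#' @param edge_width Width of the edge band in rows/columns.
#' @param noise_sd Standard deviation of Gaussian noise on log-opacity.
#' @param dropout_prob Probability a colony is missing (in \[0, 1)).
#' @param effects Planted effects: data.frame with columns `gene`,
#'   `condition` (label), `multiplier` (> 0), or `NULL` for none. Use
#'   `effect_fraction`/`effect_multiplier` to plant a random sparse set.
#' @param effect_fraction If `effects` is `NULL`, fraction of
#'   gene x condition pairs receiving a planted effect.
#' @param effect_multiplier Multiplier for randomly planted effects
#'   (e.g. 0.5 = 2-fold growth defect).
#' @param baseline Per-gene baseline opacities (> 0); drawn lognormal
#'   (meanlog log(1e4), sdlog 0.25) when `NULL`.
#' @param seed Integer seed for truth generation and the default
#'   simulation seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes, conditions, n_replicates = 3L,
                       n_rows = 32L, n_cols = 48L,
                       surface_amplitude = 0.3, edge_multiplier = 1.3,
                       edge_width = 2L, noise_sd = 0.15, dropout_prob = 0.02,
                       effects = NULL, effect_fraction = 0,
                       effect_multiplier = 0.5,
                       baseline = NULL, seed = 1L) {
  if (n_genes > n_rows * n_cols)
    stop("n_genes exceeds grid capacity")
  if (edge_multiplier <= 0) stop("edge_multiplier must be > 0")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)")
  n_replicates <- rep_len(as.integer(n_replicates), nrow(conditions))

  rng <- local_rng(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(baseline)) {
    baseline <- stats::rlnorm(n_genes, meanlog = log(1e4), sdlog = 0.25)
  } else {
    baseline <- rep_len(baseline, n_genes)
  }
  if (any(baseline <= 0)) stop("baseline opacities must be > 0")
  names(baseline) <- genes

  # one plate per (condition, replicate)
  plates <- data.frame(
    condition = rep(conditions$label, n_replicates),
    replicate = unlist(lapply(n_replicates, seq_len)),
    stringsAsFactors = FALSE
  )
  plates$plate <- paste0(plates$condition, ":rep", plates$replicate)

  # layout: genes placed row-major
  pos <- seq_len(n_genes)
  layout <- data.frame(
    row = ((pos - 1L) %/% n_cols) + 1L,
    col = ((pos - 1L) %% n_cols) + 1L,
    gene = genes,
    stringsAsFactors = FALSE
  )

  # per-plate quartic log-surface, geometric mean 1 over occupied
  # positions, sd scaled to log1p(amplitude)
  basis <- poly_basis(layout$row, layout$col, n_rows, n_cols)
  surface_coeffs <- vector("list", nrow(plates))
  names(surface_coeffs) <- plates$plate
  for (p in seq_len(nrow(plates))) {
    beta <- c(0, stats::rnorm(ncol(basis) - 1L))
    s <- drop(basis %*% beta)
    if (surface_amplitude > 0 && stats::sd(s) > 0) {
      scale <- log1p(surface_amplitude) / stats::sd(s)
      beta <- beta * scale
      s <- s * scale
    } else {
      beta <- beta * 0
      s <- s * 0
    }
    beta[1] <- -mean(s)   # geometric mean 1
    names(beta) <- colnames(basis)
    surface_coeffs[[p]] <- beta
  }

  if (is.null(effects) && effect_fraction > 0) {
    n_pairs <- n_genes * nrow(conditions)
    n_eff <- round(effect_fraction * n_pairs)
    pick <- sample.int(n_pairs, n_eff)
    effects <- data.frame(
      gene = genes[((pick - 1L) %% n_genes) + 1L],
      condition = conditions$label[((pick - 1L) %/% n_genes) + 1L],
      multiplier = effect_multiplier,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(effects)) {
    effects <- data.frame(gene = character(0), condition = character(0),
                          multiplier = numeric(0), stringsAsFactors = FALSE)
  }
  if (any(effects$multiplier <= 0)) stop("effect multipliers must be > 0")
  if (!all(effects$gene %in% genes))
    stop("planted effect references unknown gene")
  if (!all(effects$condition %in% conditions$label))
    stop("planted effect references unknown condition")
  restore_rng(rng)

  structure(list(
    n_genes = n_genes, genes = genes, conditions = conditions,
    n_replicates = n_replicates, plates = plates, layout = layout,
    n_rows = n_rows, n_cols = n_cols,
    surface_amplitude = surface_amplitude,
    surface_coeffs = surface_coeffs,
    edge_multiplier = edge_multiplier, edge_width = edge_width,
    noise_sd = noise_sd, dropout_prob = dropout_prob,
    effects = effects, baseline = baseline, seed = seed
  ), class = "sim_config")
}

# Seed the RNG locally, returning the previous state for restoration, so
# package functions do not clobber the caller's random stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Simulate a colony screen
#'
#' Draws colony opacities under the multiplicative model
#' `opacity = baseline(gene) * effect(gene, condition) * surface(row, col)
#' * edge(row, col) * exp(eps)`, `eps ~ N(0, noise_sd^2)`, one plate per
#' (condition, replicate). Dropped-out colonies are emitted with opacity 0
#' and flag `missing`. Identical `(config, seed)` gives identical output.
#'
#' @param config A [sim_config()].
#' @param seed Seed for noise and dropout; defaults to `config$seed`.
#' @return A list of class `sim_screen`: `colonies` (a `colony_table`),
#'   `layout`, `plates` (plate metadata: plate, condition label, replicate),
#'   `conditions`, and `truth` (class `sim_truth`: planted `effects`,
#'   per-plate log-surface values `surface`, `dropout` positions,
#'   `baseline`, and the generating `config`).
#' @export
simulate_screen <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))

  lay <- config$layout
  n <- nrow(lay)
  plates <- config$plates
  basis <- poly_basis(lay$row, lay$col, config$n_rows, config$n_cols)

  edge <- lay$row <= config$edge_width |
    lay$col <= config$edge_width |
    lay$row > config$n_rows - config$edge_width |
    lay$col > config$n_cols - config$edge_width
  log_edge <- ifelse(edge, log(config$edge_multiplier), 0)

  # planted effect lookup: genes x conditions log-multiplier
  eff <- matrix(0, nrow = config$n_genes, ncol = nrow(config$conditions),
                dimnames = list(config$genes, config$conditions$label))
  if (nrow(config$effects) > 0) {
    eff[cbind(match(config$effects$gene, config$genes),
              match(config$effects$condition, config$conditions$label))] <-
      log(config$effects$multiplier)
  }

  base_log <- log(config$baseline[lay$gene])

  out <- vector("list", nrow(plates))
  surfaces <- vector("list", nrow(plates))
  names(surfaces) <- plates$plate
  dropouts <- vector("list", nrow(plates))
  for (p in seq_len(nrow(plates))) {
    s <- drop(basis %*% config$surface_coeffs[[plates$plate[p]]])
    surfaces[[p]] <- data.frame(row = lay$row, col = lay$col, log_surface = s)
    log_op <- base_log + eff[, plates$condition[p]][lay$gene] + s + log_edge +
      stats::rnorm(n, 0, config$noise_sd)
    opacity <- exp(log_op)
    drop_here <- stats::runif(n) < config$dropout_prob
    opacity[drop_here] <- 0
    flags <- rep("", n)
    flags <- flag_add(flags, "missing", drop_here)
    out[[p]] <- data.frame(
      plate = plates$plate[p], row = lay$row, col = lay$col,
      gene = lay$gene, size = opacity / 10, opacity = opacity,
      circularity = NA_real_, flags = flags, stringsAsFactors = FALSE
    )
    dropouts[[p]] <- data.frame(plate = rep(plates$plate[p], sum(drop_here)),
                                row = lay$row[drop_here],
                                col = lay$col[drop_here],
                                stringsAsFactors = FALSE)
  }
  colonies <- do.call(rbind, out)
  class(colonies) <- c("colony_table", "data.frame")

  truth <- structure(list(
    effects = config$effects, surface = surfaces,
    dropout = do.call(rbind, dropouts), baseline = config$baseline,
    config = config
  ), class = "sim_truth")

  structure(list(colonies = colonies, layout = config$layout,
                 plates = plates, conditions = config$conditions,
                 truth = truth),
            class = "sim_screen")
}

#' @export
print.sim_screen <- function(x, ...) {
  cat(sprintf(
    "sim_screen: %d genes, %d conditions, %d plates (%d x %d grid)\n",
    x$truth$config$n_genes, nrow(x$conditions), nrow(x$plates),
    x$truth$config$n_rows, x$truth$config$n_cols))
  cat(sprintf("  planted effects: %d; dropout positions: %d\n",
              nrow(x$truth$effects), nrow(x$truth$dropout)))
  invisible(x)
}

#' Confusion counts of phenotype calls against planted truth
#'
#' A call is a true positive iff a planted effect exists for that
#' gene x condition pair with matching sign (multiplier < 1 corresponds to
#' a sensitive/negative call, multiplier > 1 to a resistant/positive one).
#' A call on an unplanted pair, or with the wrong sign, is a false
#' positive; a planted pair with no matching call is a false negative.
#'
#' @param calls Phenotype calls from [call_phenotypes()] (data.frame with
#'   `gene`, `condition`, `sign`).
#' @param truth A `sim_truth` (or a `sim_config`).
#' @return A list: counts `tp`, `fp`, `fn`, `tn`; `fdr` = FP/(FP+TP) (`NA`
#'   when there are no calls); `recall` = TP/(TP+FN) (`NA` when nothing was
#'   planted); `sign_accuracy` among calls on planted pairs (`NA` if none);
#'   and `false_call_rate` = FP / (number of unplanted pairs).
#' @export
truth_confusion <- function(calls, truth) {
  config <- if (inherits(truth, "sim_config")) truth else truth$config
  effects <- if (inherits(truth, "sim_config")) truth$effects else truth$effects
  genes <- config$genes
  cond <- config$conditions$label
  n_pairs <- length(genes) * length(cond)

  if (nrow(calls) > 0) {
    if (!all(calls$gene %in% genes) || !all(calls$condition %in% cond))
      stop("calls refer to genes/conditions outside the simulated universe")
  }
  key <- function(g, c) paste(g, c, sep = "\r")
  planted_sign <- ifelse(effects$multiplier < 1, "sensitive", "resistant")
  planted <- stats::setNames(planted_sign, key(effects$gene, effects$condition))

  call_keys <- key(calls$gene, calls$condition)
  on_planted <- call_keys %in% names(planted)
  tp <- sum(on_planted & calls$sign == planted[call_keys])
  fp <- nrow(calls) - tp
  fn <- length(planted) - tp
  tn <- n_pairs - tp - fp - fn

  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    fdr = if (tp + fp == 0) NA_real_ else fp / (tp + fp),
    recall = if (length(planted) == 0) NA_real_ else tp / length(planted),
    sign_accuracy = if (!any(on_planted)) NA_real_ else
      mean(calls$sign[on_planted] == planted[call_keys[on_planted]]),
    false_call_rate = if (n_pairs == length(planted)) NA_real_ else
      fp / (n_pairs - length(planted))
  )
}
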