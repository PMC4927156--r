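#' @title Per-plate cleaning and normalization
#' @description The pipeline's cleaning stack, applied in fixed order:
#'   positional masking, robust quartic surface normalization of
#'   log-opacity, per-condition power transformation, per-plate variance
#'   normalization, and reliability filtering.
#' @name normalization
NULL

#' Mask plate positions
#'
#' Flags manually excluded positions (e.g. recurrent pinning problems) as
#' `masked`. Masked records are excluded from every downstream fit and
#' score but remain in the table; the record count never changes.
#'
#' @param tbl A `colony_table`.
#' @param mask Data.frame of positions to mask with columns `row`, `col`
#'   and optionally `plate` (absent = applies to all plates).
#' @return The colony table with `masked` flags added.
#' @export
apply_position_mask <- function(tbl, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(tbl)
  if (any(mask$row < 1L) || any(mask$col < 1L) ||
      any(mask$row > max(tbl$row)) || any(mask$col > max(tbl$col)))
    stop("mask position outside the plate grid")
  if ("plate" %in% names(mask)) {
    hit <- paste(tbl$plate, tbl$row, tbl$col) %in%
      paste(mask$plate, mask$row, mask$col)
  } else {
    hit <- paste(tbl$row, tbl$col) %in% paste(mask$row, mask$col)
  }
  tbl$flags <- flag_add(tbl$flags, "masked", hit)
  tbl
}

#' Robust quartic surface normalization of one plate
#'
#' Fits a bivariate polynomial of total degree 4 (15 terms) to log-opacity
#' by iteratively trimmed least squares: ordinary least squares, then drop
#' points whose residual exceeds `trim_mad` times the MAD of residuals,
#' refit, up to `max_iter` iterations. Colony arrays show smooth
#' multiplicative pinning/nutrient gradients; fitting in log space makes
#' them additive and the fit linear. The trimming keeps dead or
#' contaminated colonies from dragging the surface.
#'
#' The normalized opacity is `opacity / exp(fitted - mean(fitted))`, i.e.
#' the fitted surface is removed but its plate-mean level (and hence the
#' plate's median log-opacity, up to the mean/median convention) is
#' preserved; the removed surface has geometric mean 1.
#'
#' @param tbl Colony table restricted to one plate.
#' @param n_rows,n_cols Grid dimensions (defaults: observed maxima).
#' @param degree Polynomial total degree (4).
#' @param trim_mad Residual trim threshold in MAD units (3).
#' @param max_iter Maximum trimming iterations (5).
#' @param min_colonies Minimum reliable colonies required (30); with 15
#'   coefficients anything less leaves no degrees-of-freedom headroom.
#' @return A list: `tbl` (records with `opacity` replaced by its normalized
#'   value, unreliable records untouched) and `fit`, a `surface_fit` with
#'   elements `coefficients` (on the shared scaled-coordinate basis),
#'   `fitted` (per-record log-surface, mean-centered), `trimmed` (logical,
#'   points excluded by the robustness trimming), `n_used`.
#' @export
surface_normalize <- function(tbl, n_rows = max(tbl$row),
                              n_cols = max(tbl$col), degree = 4L,
                              trim_mad = 3, max_iter = 5L,
                              min_colonies = 30L) {
  if (length(unique(tbl$plate)) > 1L)
    stop("surface_normalize expects records from a single plate")
  use <- colony_reliable(tbl) & tbl$opacity > 0
  if (sum(use) < min_colonies)
    stop(sprintf(
      "too few reliable colonies for surface fit: %d < %d (15 coefficients)",
      sum(use), min_colonies))

  X <- poly_basis(tbl$row, tbl$col, n_rows, n_cols, degree)
  y <- log(tbl$opacity)
  keep <- use
  beta <- NULL
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    res <- y - drop(X %*% beta)
    s <- stats::mad(res[keep])
    if (s == 0) break
    keep_new <- use & abs(res) <= trim_mad * s
    if (sum(keep_new) < min_colonies) break
    if (identical(keep_new, keep)) break
    keep <- keep_new
  }
  fitted <- drop(X %*% beta)
  center <- mean(fitted[use])
  fitted_c <- fitted - center
  beta_c <- beta
  beta_c[1] <- beta_c[1] - center

  out <- tbl
  adj <- exp(fitted_c)
  ok <- colony_reliable(tbl) & tbl$opacity > 0
  out$opacity[ok] <- tbl$opacity[ok] / adj[ok]

  fit_obj <- structure(list(
    coefficients = beta_c, fitted = fitted_c,
    trimmed = use & !keep, n_used = sum(keep),
    n_rows = n_rows, n_cols = n_cols, degree = degree
  ), class = "surface_fit")
  list(tbl = out, fit = fit_obj)
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf(
    "surface_fit: degree %d (%d coefficients), %d colonies used, %d trimmed\n",
    x$degree, length(x$coefficients), x$n_used, sum(x$trimmed)))
  cat(sprintf("  log-surface range: [%.3f, %.3f]\n",
              min(x$fitted), max(x$fitted)))
  invisible(x)
}

#' Fit a Box-Cox power transform
#'
#' Chooses the exponent lambda on the grid \[-2, 2\] in steps of 0.05 by
#' maximizing the Box-Cox profile log-likelihood (via [MASS::boxcox()]),
#' damping the influence of extreme values on downstream statistics. The
#' transform is `(x^lambda - 1)/lambda` (log for lambda = 0), strictly
#' increasing on positive data, so ranks are preserved.
#'
#' @param x Positive numeric values (after adding `shift`).
#' @param shift Non-negative shift added before transforming.
#' @param lambda_grid Candidate exponents.
#' @return A list of class `power_transform`: `lambda`, `shift`.
#' @export
power_transform_fit <- function(x, shift = 0,
                                lambda_grid = seq(-2, 2, by = 0.05)) {
  x <- x[is.finite(x)]
  if (shift < 0) stop("shift must be >= 0")
  x <- x + shift
  if (any(x <= 0))
    stop("power transform requires positive values (after shift)")
  d <- data.frame(x = x)
  bc <- MASS::boxcox(x ~ 1, data = d, lambda = lambda_grid, plotit = FALSE,
                     interp = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  structure(list(lambda = lambda, shift = shift), class = "power_transform")
}

#' Apply a power transform
#'
#' @param x Numeric values.
#' @param pt A `power_transform` from [power_transform_fit()].
#' @return Transformed values.
#' @export
power_transform_apply <- function(x, pt) {
  y <- x + pt$shift
  if (any(y[is.finite(y)] <= 0))
    stop("power transform requires positive values (after shift)")
  if (abs(pt$lambda) < 1e-12) log(y) else (y^pt$lambda - 1) / pt$lambda
}

#' Variance normalization across plates
#'
#' Centers each column group of a screen matrix on its median and rescales
#' it so its interquartile range equals a common reference scale (default:
#' the median IQR across groups). Equalizing spread across replicate plates
#' improves between-plate reproducibility of per-gene values. Groups with
#' zero IQR are centered but left unscaled, with a warning.
#'
#' @param m A `screen_matrix` (stage `raw` or `normalized`).
#' @param groups Factor/character of length `ncol(m)` assigning columns to
#'   plates or conditions; default: each column its own group.
#' @param reference_scale Target IQR; default median group IQR.
#' @param min_values Minimum unmasked values a group must have (10).
#' @return The rescaled `screen_matrix`; masked cells untouched.
#' @export
variance_normalize <- function(m, groups = NULL, reference_scale = NULL,
                               min_values = 10L) {
  stopifnot(inherits(m, "screen_matrix"))
  if (is.null(groups)) groups <- colnames(m$values)
  groups <- as.character(groups)
  if (length(groups) != ncol(m$values))
    stop("groups must have one entry per column")

  vals <- m$values
  vals[!m$mask] <- NA_real_
  glev <- unique(groups)
  med <- iqr <- stats::setNames(numeric(length(glev)), glev)
  for (g in glev) {
    v <- vals[, groups == g]
    v <- v[!is.na(v)]
    if (length(v) < min_values)
      stop(sprintf("group '%s' has %d unmasked values (< %d)",
                   g, length(v), min_values))
    med[g] <- stats::median(v)
    iqr[g] <- stats::IQR(v)
  }
  if (is.null(reference_scale)) reference_scale <- stats::median(iqr)
  for (g in glev) {
    j <- groups == g
    scale <- if (iqr[g] == 0) {
      warning(sprintf("group '%s' has zero IQR; centered but not rescaled", g))
      1
    } else reference_scale / iqr[g]
    vals[, j] <- (vals[, j] - med[g]) * scale
  }
  new_vals <- m$values
  new_vals[m$mask] <- vals[m$mask]
  screen_matrix(new_vals, m$conditions, mask = m$mask, stage = m$stage)
}

#' Reliability filter
#'
#' Removes genes, then conditions, whose fraction of reliable (unmasked)
#' measurements is below `threshold`, iterating to a fixed point: dropping
#' a condition can push a gene below threshold and vice versa. The
#' boundary is exclusive: exactly `threshold` is retained.
#'
#' @param m A `screen_matrix`.
#' @param threshold Minimum reliable fraction in (0, 1\]; default 0.75.
#' @return The filtered `screen_matrix`, with attributes `dropped_genes`
#'   and `dropped_conditions` listing removed identifiers.
#' @export
filter_low_coverage <- function(m, threshold = 0.75) {
  stopifnot(inherits(m, "screen_matrix"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  dropped_g <- character(0)
  dropped_c <- character(0)
  repeat {
    changed <- FALSE
    rf <- reliable_frac_rows(m)
    bad <- rf < threshold
    if (any(bad)) {
      dropped_g <- c(dropped_g, genes_of(m)[bad])
      if (all(bad)) stop("reliability filter removed every gene")
      m <- m[!bad, ]
      changed <- TRUE
    }
    cf <- reliable_frac_cols(m)
    bad <- cf < threshold
    if (any(bad)) {
      dropped_c <- c(dropped_c, m$conditions$label[bad])
      if (all(bad)) stop("reliability filter removed every condition")
      m <- m[, !bad]
      changed <- TRUE
    }
    if (!changed) break
  }
  attr(m, "dropped_genes") <- dropped_g
  attr(m, "dropped_conditions") <- dropped_c
  m
}

#' Build a raw screen matrix from colony records
#'
#' Pivots a colony table (with gene identifiers attached) into a genes x
#' plate-columns `screen_matrix`. Records flagged `missing` or `masked`
#' come back masked.
#'
#' @param tbl A `colony_table` covering one or more plates.
#' @param plates Plate metadata: data.frame with `plate`, `condition`
#'   (label), `replicate`.
#' @return A `screen_matrix` with stage `"raw"` and one column per plate.
#' @export
colonies_to_matrix <- function(tbl, plates) {
  if (any(is.na(tbl$gene))) stop("colony records lack gene identifiers")
  genes <- sort(unique(tbl$gene))
  pi <- match(tbl$plate, plates$plate)
  if (any(is.na(pi))) stop("colony record on unknown plate")
  vals <- matrix(NA_real_, nrow = length(genes), ncol = nrow(plates),
                 dimnames = list(genes, plates$plate))
  ok <- colony_reliable(tbl) & tbl$opacity > 0
  vals[cbind(match(tbl$gene, genes), pi)[ok, , drop = FALSE]] <-
    tbl$opacity[ok]
  u <- unique(plates$condition)
  pu <- parse_condition_label(u)
  cond <- pu[match(plates$condition, u), , drop = FALSE]
  rownames(cond) <- NULL
  cond$replicate <- plates$replicate
  cond$label <- plates$plate
  screen_matrix(vals, cond, mask = is.finite(vals), stage = "raw")
}

#' Run the normalization stack on a screen
#'
#' Fixed stage order: positional masking, per-plate robust quartic surface
#' normalization, per-condition power transformation, per-plate variance
#' normalization. Returns the normalized matrix (one column per plate)
#' ready for [fitness_scores()].
#'
#' @param screen A `sim_screen`, or a list with elements `colonies`
#'   (a `colony_table` with genes attached) and `plates` (plate metadata as
#'   in [colonies_to_matrix()]).
#' @param mask Optional positional mask (see [apply_position_mask()]).
#' @param surface Logical, apply surface normalization (default TRUE).
#' @param power Logical, apply the per-condition power transform.
#' @param variance Logical, apply per-plate variance normalization.
#' @param ... Passed to [surface_normalize()].
#' @return A list: `matrix` (stage `"normalized"`), `surface_fits` (one
#'   `surface_fit` per plate), `power_transforms` (one per condition).
#' @export
normalize_screen <- function(screen, mask = NULL, surface = TRUE,
                             power = TRUE, variance = TRUE, ...) {
  tbl <- screen$colonies
  plates <- screen$plates
  if (!is.null(mask)) tbl <- apply_position_mask(tbl, mask)

  fits <- list()
  if (surface) {
    parts <- split(seq_len(nrow(tbl)), tbl$plate)
    for (p in names(parts)) {
      sn <- surface_normalize(tbl[parts[[p]], , drop = FALSE], ...)
      tbl$opacity[parts[[p]]] <- sn$tbl$opacity
      fits[[p]] <- sn$fit
    }
  }

  m <- colonies_to_matrix(tbl, plates)

  pts <- list()
  if (power) {
    vals <- m$values
    for (cond in unique(plates$condition)) {
      j <- plates$condition == cond
      sub <- vals[, j, drop = FALSE]
      msk <- m$mask[, j, drop = FALSE]
      pt <- power_transform_fit(sub[msk])
      sub[msk] <- power_transform_apply(sub[msk], pt)
      vals[, j] <- sub
      pts[[cond]] <- pt
    }
    m <- screen_matrix(vals, m$conditions, mask = m$mask, stage = "raw")
  }

  if (variance) {
    m <- variance_normalize(m, groups = colnames(m$values))
  }
  m$stage <- "normalized"
  list(matrix = m, surface_fits = fits, power_transforms = pts)
}
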