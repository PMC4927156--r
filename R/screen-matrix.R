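#' Screen matrix container
#'
#' The central container of the pipeline: a genes x conditions numeric
#' matrix together with a reliability mask and a stage label. The same
#' container carries raw opacities (one column per plate), normalized
#' values (one column per condition replicate), and fitness scores (one
#' column per condition).
#'
#' @param values Numeric matrix, genes in rows. Row names are gene
#'   identifiers; they are required.
#' @param conditions Condition data.frame as from [condition_meta()], one
#'   row per column of `values`.
#' @param mask Logical matrix of the same dimension; `TRUE` marks a reliable
#'   measurement. Defaults to `is.finite(values)`.
#' @param stage One of `"raw"`, `"normalized"`, `"score"`.
#' @return An object of class `screen_matrix`: a list with elements
#'   `values`, `mask`, `conditions`, `stage`.
#' @export
screen_matrix <- function(values, conditions, mask = NULL,
                          stage = c("raw", "normalized", "score")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene row names")
  if (!is.data.frame(conditions) || nrow(conditions) != ncol(values))
    stop("conditions must have one row per column of values")
  if (is.null(mask)) mask <- is.finite(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values)))
    stop("mask and values dimensions differ")
  mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  if (any(!is.finite(values[mask])))
    stop("values must be finite wherever mask is TRUE")
  colnames(values) <- conditions$label
  dimnames(mask) <- dimnames(values)
  structure(
    list(values = values, mask = mask, conditions = conditions, stage = stage),
    class = "screen_matrix"
  )
}

#' @export
dim.screen_matrix <- function(x) dim(x$values)

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("screen_matrix [%s]: %d genes x %d conditions (%.1f%% reliable)\n",
              x$stage, nrow(x$values), ncol(x$values),
              100 * mean(x$mask)))
  nb <- length(unique(x$conditions$batch))
  cat(sprintf("  batches: %d; replicate columns: %s\n", nb,
              if (any(x$conditions$replicate > 1L)) "yes" else "no"))
  invisible(x)
}

#' @export
as.matrix.screen_matrix <- function(x, ...) {
  v <- x$values
  v[!x$mask] <- NA_real_
  v
}

#' Subset a screen matrix
#'
#' @param x A `screen_matrix`.
#' @param i,j Gene (row) and condition (column) indices.
#' @param ... Unused.
#' @return A `screen_matrix` restricted to the selected genes/conditions.
#' @export
`[.screen_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  screen_matrix(x$values[i, j, drop = FALSE],
                x$conditions[j, , drop = FALSE],
                mask = x$mask[i, j, drop = FALSE],
                stage = x$stage)
}

genes_of <- function(x) rownames(x$values)

# Fraction of reliable cells per row / per column.
reliable_frac_rows <- function(x) rowMeans(x$mask)
reliable_frac_cols <- function(x) colMeans(x$mask)
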