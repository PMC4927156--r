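#' @title Colony table input/output (Iris dialect)
#' @description Readers and writers for the delimited tables produced by
#'   colony-quantification software: one row per colony with plate
#'   identifier, grid position, and measurements (pixel area "size", summed
#'   pixel intensity "opacity", circularity). Grid coordinates are 1-based
#'   and row-major, matching plate photographs.
#' @name plate_io
NULL

# Default mapping from canonical field -> acceptable column names (matched
# case-insensitively). Quantification software versions differ in header
# spelling, so the dialect is configurable.
default_dialect <- function() {
  list(
    plate       = c("plate", "plate_id", "plateid"),
    row         = c("row"),
    col         = c("col", "column"),
    gene        = c("gene", "strain", "strain_id", "mutant"),
    size        = c("size", "colony size", "area"),
    opacity     = c("opacity", "colony opacity", "intensity"),
    circularity = c("circularity", "roundness")
  )
}

flag_has <- function(flags, what) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ";", fixed = TRUE),
         function(f) what %in% f, logical(1))
}

flag_add <- function(flags, what, where = TRUE) {
  flags <- ifelse(is.na(flags), "", flags)
  add <- where & !flag_has(flags, what)
  flags[add] <- ifelse(nzchar(flags[add]), paste(flags[add], what, sep = ";"),
                       what)
  flags
}

#' Is a colony record reliable?
#'
#' A record is reliable unless flagged `missing` (no colony grew or the
#' measurement could not be parsed) or `masked` (manually excluded plate
#' position).
#'
#' @param tbl A colony table as returned by [read_colony_table()].
#' @return Logical vector, one element per record.
#' @export
colony_reliable <- function(tbl) {
  !flag_has(tbl$flags, "missing") & !flag_has(tbl$flags, "masked")
}

guess_sep <- function(header_line) {
  if (grepl("\t", header_line)) "\t" else ","
}

#' Read a colony quantification table
#'
#' Parses Iris-style delimited output (comma- or tab-separated, autodetected
#' from the header). Column names are matched case-insensitively against the
#' dialect descriptor. `plate`, `row`, `col` and `opacity` are mandatory;
#' absent `size`/`circularity` columns become `NA`. Rows whose opacity cell
#' is empty or non-numeric are kept with opacity 0 and flag `missing`:
#' absent growth is data, and the flag marks the measurement unreliable.
#'
#' @param path Path to the delimited file.
#' @param dialect Named list mapping canonical fields (`plate`, `row`, `col`,
#'   `gene`, `size`, `opacity`, `circularity`) to acceptable header names.
#'   Defaults cover common spellings.
#' @param low_circularity Optional threshold in \[0,1\]; colonies below it
#'   get flag `low_circularity` (informational, not excluded).
#' @return A data.frame of class `colony_table` with columns `plate`, `row`,
#'   `col`, `gene`, `size`, `opacity`, `circularity`, `flags`.
#' @export
read_colony_table <- function(path, dialect = default_dialect(),
                              low_circularity = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty colony table: ", path)
  sep <- guess_sep(lines[[1]])
  raw <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", strip.white = TRUE)
  hdr <- tolower(trimws(colnames(raw)))

  pick <- function(field) {
    hit <- which(hdr %in% tolower(dialect[[field]]))
    if (length(hit) == 0L) return(NA_integer_)
    hit[[1]]
  }
  idx <- vapply(names(default_dialect()), pick, integer(1))
  mandatory <- c("plate", "row", "col", "opacity")
  absent <- mandatory[is.na(idx[mandatory])]
  if (length(absent) > 0L)
    stop("colony table is missing mandatory column(s): ",
         paste(absent, collapse = ", "))

  get_col <- function(field) {
    if (is.na(idx[[field]])) rep(NA_character_, nrow(raw))
    else raw[[idx[[field]]]]
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))

  opacity_raw <- get_col("opacity")
  opacity <- num_or_na(opacity_raw)
  missing_flag <- is.na(opacity) | opacity == 0
  opacity[is.na(opacity)] <- 0

  tbl <- data.frame(
    plate = get_col("plate"),
    row   = as.integer(num_or_na(get_col("row"))),
    col   = as.integer(num_or_na(get_col("col"))),
    gene  = get_col("gene"),
    size  = num_or_na(get_col("size")),
    opacity = opacity,
    circularity = num_or_na(get_col("circularity")),
    flags = "",
    stringsAsFactors = FALSE
  )
  if (any(is.na(tbl$row)) || any(is.na(tbl$col)) ||
      any(tbl$row < 1L) || any(tbl$col < 1L))
    stop("row/col must be integers >= 1")
  bad_circ <- !is.na(tbl$circularity) &
    (tbl$circularity < 0 | tbl$circularity > 1)
  if (any(bad_circ)) stop("circularity must lie in [0, 1]")

  key <- paste(tbl$plate, tbl$row, tbl$col)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (plate, row, col) position: ", d)
  }

  tbl$flags <- flag_add(tbl$flags, "missing", missing_flag)
  if (!is.null(low_circularity))
    tbl$flags <- flag_add(tbl$flags, "low_circularity",
                          !is.na(tbl$circularity) &
                            tbl$circularity < low_circularity)
  class(tbl) <- c("colony_table", "data.frame")
  tbl
}

#' Write a colony table
#'
#' Emits the canonical tab-separated dialect readable by
#' [read_colony_table()]; round-trips values and flags.
#'
#' @param tbl A `colony_table`.
#' @param path Output path.
#' @param sep Field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_colony_table <- function(tbl, path, sep = "\t") {
  out <- data.frame(
    plate = tbl$plate, row = tbl$row, column = tbl$col,
    gene = tbl$gene, size = tbl$size,
    opacity = ifelse(flag_has(tbl$flags, "missing") & tbl$opacity == 0,
                     "", format(tbl$opacity, digits = 15, trim = TRUE,
                                scientific = FALSE)),
    circularity = tbl$circularity,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write a plate layout
#'
#' A layout maps grid positions to strain (gene) identifiers and applies to
#' every plate of the screen. Delimited text with header columns `row`,
#' `col`(`umn`) and `gene`/`strain`.
#'
#' @param path File path.
#' @return A data.frame with columns `row`, `col`, `gene`.
#' @export
read_plate_layout <- function(path) {
  lines <- readLines(path)
  sep <- guess_sep(lines[[1]])
  raw <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- tolower(trimws(colnames(raw)))
  want <- function(names, what) {
    hit <- which(hdr %in% names)
    if (length(hit) == 0L) stop("layout is missing column: ", what)
    raw[[hit[[1]]]]
  }
  out <- data.frame(
    row  = as.integer(want(c("row"), "row")),
    col  = as.integer(want(c("col", "column"), "col")),
    gene = as.character(want(c("gene", "strain", "strain_id"), "gene")),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(paste(out$row, out$col)))
    stop("duplicate (row, col) position in layout")
  out
}

#' @rdname read_plate_layout
#' @param layout Layout data.frame.
#' @export
write_plate_layout <- function(layout, path) {
  utils::write.table(layout[, c("row", "col", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach gene identifiers to colony records
#'
#' Joins a plate layout onto a colony table by grid position. Positions with
#' no layout entry keep their existing `gene` (or `NA`).
#'
#' @param tbl A `colony_table`.
#' @param layout Layout data.frame from [read_plate_layout()].
#' @return The colony table with its `gene` column filled in.
#' @export
apply_layout <- function(tbl, layout) {
  i <- match(paste(tbl$row, tbl$col), paste(layout$row, layout$col))
  hit <- !is.na(i)
  tbl$gene[hit] <- layout$gene[i[hit]]
  tbl
}

#' Read a score matrix (deposited-dataset dialect)
#'
#' Tab-delimited: first header row holds gene names, each following row a
#' condition label (`"name [conc] {batch}"`) followed by one value per gene.
#' Empty cells are unreliable measurements and come back masked. Internally
#' the matrix is stored genes x conditions.
#'
#' @param path File path.
#' @param stage Stage label for the resulting matrix, default `"score"`.
#' @return A [screen_matrix()].
#' @export
read_score_matrix <- function(path, stage = "score") {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("score matrix needs a header and one row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; pad to declared width
  header <- cells[[1]]
  genes <- header[-1]
  width <- length(header)
  n_cond <- length(lines) - 1L
  vals <- matrix(NA_real_, nrow = length(genes), ncol = n_cond)
  labels <- character(n_cond)
  for (i in seq_len(n_cond)) {
    row <- cells[[i + 1L]]
    if (length(row) < width) row <- c(row, rep("", width - length(row)))
    if (length(row) != width)
      stop(sprintf("ragged row %d: %d fields, expected %d",
                   i + 1L, length(row), width))
    labels[i] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    v[!nzchar(trimws(row[-1]))] <- NA_real_
    vals[, i] <- v
  }
  conditions <- parse_condition_label(labels)
  rownames(vals) <- genes
  screen_matrix(vals, conditions, mask = is.finite(vals), stage = stage)
}

#' Write a score matrix
#'
#' Inverse of [read_score_matrix()]: conditions in rows, genes in columns,
#' masked cells written empty. Values keep 15 significant digits so that a
#' round-trip preserves them well beyond measurement precision.
#'
#' @param m A [screen_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(m, path) {
  vals <- m$values
  txt <- matrix("", nrow = nrow(vals), ncol = ncol(vals))
  txt[m$mask] <- format(vals[m$mask], digits = 15, trim = TRUE,
                        scientific = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("condition", rownames(vals)), collapse = "\t"), con)
  for (j in seq_len(ncol(vals))) {
    writeLines(paste(c(m$conditions$label[j], txt[, j]), collapse = "\t"), con)
  }
  invisible(path)
}
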