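#' Construct condition metadata
#'
#' A condition is one stress applied to the arrayed library: a name, a
#' concentration (kept as a string so units survive round-trips), a batch
#' number grouping conditions that were screened and normalized together,
#' a replicate index, and a control flag. Batch 0 is reserved for conditions
#' integrated from a prior reference screen.
#'
#' @param name Condition name, e.g. `"kasugamycin"`.
#' @param concentration Concentration with units, e.g. `"25mM"`. Stored as
#'   character.
#' @param batch Non-negative integer batch identifier. Default 0.
#' @param replicate Positive integer replicate index. Default 1.
#' @param is_control Logical, whether the condition is an untreated control.
#' @return A data.frame with one row per condition and columns `name`,
#'   `concentration`, `batch`, `replicate`, `is_control`, and `label`
#'   (the canonical `"name [conc] {batch}"` form).
#' @seealso [parse_condition_label()], [format_condition_label()]
#' @export
condition_meta <- function(name, concentration, batch = 0L, replicate = 1L,
                           is_control = FALSE) {
  n <- max(length(name), length(concentration), length(batch),
           length(replicate), length(is_control))
  out <- data.frame(
    name          = rep_len(as.character(name), n),
    concentration = rep_len(as.character(concentration), n),
    batch         = rep_len(as.integer(batch), n),
    replicate     = rep_len(as.integer(replicate), n),
    is_control    = rep_len(as.logical(is_control), n),
    stringsAsFactors = FALSE
  )
  if (any(out$batch < 0L)) stop("batch must be >= 0")
  if (any(out$replicate < 1L)) stop("replicate must be >= 1")
  key <- paste(out$name, out$concentration, out$batch, out$replicate)
  if (anyDuplicated(key))
    stop("duplicate (name, concentration, batch, replicate) combinations")
  out$label <- format_condition_label(out$name, out$concentration, out$batch)
  out
}

#' Format a condition label
#'
#' Canonical label dialect: condition name, concentration in square brackets,
#' batch number in curly braces, e.g. `"kasugamycin [25mM] {1}"`.
#'
#' @param name,concentration,batch Vectors as in [condition_meta()].
#' @return Character vector of labels.
#' @export
format_condition_label <- function(name, concentration, batch = 0L) {
  sprintf("%s [%s] {%d}", name, concentration, as.integer(batch))
}

#' Parse a condition label
#'
#' Inverts [format_condition_label()]. The concentration sits in square
#' brackets and the batch in curly braces; a label without braces gets
#' batch 0, the batch reserved for conditions taken over from the prior
#' integrated screen.
#'
#' @param label Character vector of labels such as `"tetracycline [1] {2}"`.
#' @return A condition data.frame as returned by [condition_meta()].
#' @export
parse_condition_label <- function(label) {
  if (length(label) == 0L) stop("label must be non-empty")
  label <- as.character(label)
  if (any(is.na(label)) || any(!nzchar(trimws(label))))
    stop("label must be non-empty")

  parse_one <- function(s) {
    raw <- s
    s <- trimws(s)
    n_open  <- lengths(regmatches(s, gregexpr("\\[", s)))
    n_close <- lengths(regmatches(s, gregexpr("\\]", s)))
    b_open  <- lengths(regmatches(s, gregexpr("\\{", s)))
    b_close <- lengths(regmatches(s, gregexpr("\\}", s)))
    if (n_open != n_close || b_open != b_close)
      stop(sprintf("unbalanced brackets in condition label: '%s'", raw))
    m <- regexec("^(.*?)\\s*\\[([^][]*)\\]\\s*(?:\\{([^{}]*)\\})?\\s*$", s)
    parts <- regmatches(s, m)[[1]]
    if (length(parts) == 0L)
      stop(sprintf("cannot parse condition label: '%s'", raw))
    name <- parts[2]
    conc <- parts[3]
    batch_str <- parts[4]
    if (!nzchar(name))
      stop(sprintf("condition label has empty name: '%s'", raw))
    if (batch_str == "" || is.na(batch_str)) {
      batch <- 0L
    } else {
      if (!grepl("^[0-9]+$", batch_str))
        stop(sprintf("batch is not a non-negative integer in label: '%s'", raw))
      batch <- as.integer(batch_str)
    }
    list(name = name, concentration = conc, batch = batch)
  }

  parsed <- lapply(label, parse_one)
  condition_meta(
    name          = vapply(parsed, `[[`, character(1), "name"),
    concentration = vapply(parsed, `[[`, character(1), "concentration"),
    batch         = vapply(parsed, `[[`, integer(1), "batch")
  )
}
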