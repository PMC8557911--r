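#' Source reference database
#'
#' A labelled set of reference 16S amplicon sequences used for source
#' attribution. Each record carries an id, a DNA sequence, and a source label
#' (`"freshwater"`, `"sewer"`, or `"human_stool"`). Sewage-side records
#' (sewer and human stool) additionally carry `sewage_p95`, the
#' 95th-percentile relative abundance of that sequence across reference raw
#' sewage samples, which feeds the inclusion filter of
#' [sewage_inclusion_filter()]. Freshwater records carry no `sewage_p95`.
#'
#' @param reference_id Character vector of unique reference ids.
#' @param sequence Character vector of DNA sequences (strict A/C/G/T),
#'   unique within the database.
#' @param source Source label(s): one of `"freshwater"`, `"sewer"`,
#'   `"human_stool"`; recycled if length 1.
#' @param sewage_p95 Numeric vector in (0, 1], required for sewer and
#'   human-stool records; must be `NA` or omitted for freshwater records.
#' @return An object of class `source_db`: a data frame with columns
#'   `reference_id`, `sequence`, `source`, `sewage_p95`.
#' @export
source_db <- function(reference_id, sequence, source, sewage_p95 = NULL) {
  n <- length(reference_id)
  if (length(sequence) != n) stop("'sequence' length mismatch", call. = FALSE)
  if (length(source) == 1L) source <- rep(source, n)
  if (length(source) != n) stop("'source' length mismatch", call. = FALSE)
  valid_sources <- c("freshwater", "sewer", "human_stool")
  if (n > 0 && !all(source %in% valid_sources)) {
    stop("'source' must be one of ", paste(valid_sources, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reference_id)) stop("duplicate reference ids", call. = FALSE)
  if (n > 0) {
    sequence <- validate_dna(sequence, "reference sequence")
    if (anyDuplicated(sequence)) {
      stop("sequences must be unique within a database", call. = FALSE)
    }
  }
  if (is.null(sewage_p95)) sewage_p95 <- rep(NA_real_, n)
  if (length(sewage_p95) != n) stop("'sewage_p95' length mismatch", call. = FALSE)
  sewage_side <- source %in% c("sewer", "human_stool")
  if (any(sewage_side & is.na(sewage_p95))) {
    stop("sewer and human_stool records require 'sewage_p95'", call. = FALSE)
  }
  ok <- is.na(sewage_p95) | (sewage_p95 > 0 & sewage_p95 <= 1)
  if (!all(ok)) stop("'sewage_p95' must lie in (0, 1]", call. = FALSE)
  sewage_p95[!sewage_side] <- NA_real_
  out <- data.frame(
    reference_id = as.character(reference_id),
    sequence = sequence,
    source = source,
    sewage_p95 = sewage_p95,
    stringsAsFactors = FALSE
  )
  class(out) <- c("source_db", "data.frame")
  out
}

is_source_db <- function(x) inherits(x, "source_db")

#' @export
print.source_db <- function(x, ...) {
  cat(sprintf("source_db: %d references (%s)\n", nrow(x),
              if (nrow(x)) paste(unique(x$source), collapse = ", ") else "empty"))
  invisible(x)
}

#' Exact full-length sequence match against a reference database
#'
#' Returns, for each query sequence, the id of a reference whose sequence is
#' identical over its full length, or `NA` when no reference matches.
#' Matching is exact string equality after uppercasing; no
#' reverse-complement search is performed (amplicons are orientation-fixed
#' by the primer protocol) and no partial or gapped alignment is attempted.
#'
#' @param sequences Character vector of query DNA sequences (strict A/C/G/T).
#' @param db A [source_db()].
#' @return Character vector of matched `reference_id`s, `NA` where unmatched.
#' @examples
#' db <- source_db("ref1", "ACGT", "freshwater")
#' exact_match(c("ACGT", "ACGA"), db)  # "ref1", NA
#' @export
exact_match <- function(sequences, db) {
  stopifnot(is_source_db(db))
  sequences <- validate_dna(sequences, "query sequence")
  if (nrow(db) == 0L) return(rep(NA_character_, length(sequences)))
  idx <- match(sequences, db$sequence)
  db$reference_id[idx]
}
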