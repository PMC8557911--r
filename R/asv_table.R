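#' ASV count table
#'
#' Container for a samples-by-ASVs matrix of nonnegative integer read counts,
#' the ASV sequences, and optional taxonomy strings. ASVs (amplicon sequence
#' variants) are exact dereplicated 16S rRNA amplicons; sequences must be over
#' the strict {A,C,G,T} alphabet (ambiguity codes are rejected) and are
#' uppercased on construction.
#'
#' @param counts Numeric matrix, samples in rows, ASVs in columns, with
#'   row (sample) and column (ASV id) names; entries nonnegative integers.
#' @param sequences Named character vector of DNA sequences; names must cover
#'   the column names of `counts`.
#' @param taxonomy Optional named character vector of taxonomy strings,
#'   passed through untouched.
#' @return An object of class `asv_table`: a list with elements `counts`,
#'   `sequences` (aligned to columns), and `taxonomy`.
#' @export
asv_table <- function(counts, sequences, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix (samples x ASVs)", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must have sample row names and ASV column names", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate ASV ids in 'counts'", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (is.null(names(sequences))) {
    stop("'sequences' must be named by ASV id", call. = FALSE)
  }
  missing_seq <- setdiff(colnames(counts), names(sequences))
  if (length(missing_seq)) {
    stop("missing sequences for ASVs: ", paste(utils::head(missing_seq, 3L), collapse = ", "),
         call. = FALSE)
  }
  seqs <- validate_dna(unname(sequences[colnames(counts)]), "ASV sequence")
  names(seqs) <- colnames(counts)
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[colnames(counts)]
    names(taxonomy) <- colnames(counts)
  }
  structure(
    list(counts = counts, sequences = seqs, taxonomy = taxonomy),
    class = "asv_table"
  )
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d samples x %d ASVs, total %d reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

is_asv_table <- function(x) inherits(x, "asv_table")

sample_ids <- function(table) rownames(table$counts)
asv_ids <- function(table) colnames(table$counts)

#' Per-sample relative abundances
#'
#' Divides each sample's counts by its total. Samples with zero total reads
#' yield `NA` proportions (their composition is undefined).
#'
#' @param table An [asv_table()].
#' @return Matrix of proportions with the same dimnames as `table$counts`;
#'   rows of samples with nonzero totals sum to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(is_asv_table(table))
  totals <- rowSums(table$counts)
  ra <- sweep(table$counts, 1, totals, "/")
  ra[totals == 0, ] <- NA_real_
  ra
}
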