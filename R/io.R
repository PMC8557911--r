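#' Read and write the pipeline's plain-text interchange formats
#'
#' Counts travel as TSV (samples in rows, ASVs in columns, first column
#' `sample_id`), sequences as FASTA, reference databases as FASTA with
#' `source=` and `sewage_p95=` key-value pairs on the description line,
#' metadata as TSV, and qPCR observations as CSV.
#'
#' @param path File path.
#' @name sewerseq-io
NULL

#' @describeIn sewerseq-io Read a samples-by-ASVs count TSV.
#' @export
read_asv_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "sample_id") {
    stop("count TSV must have 'sample_id' as its first column", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' @describeIn sewerseq-io Write a count matrix as TSV.
#' @param counts Samples-by-ASVs matrix with dimnames.
#' @export
write_asv_counts <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn sewerseq-io Read a FASTA file as a named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- names(ss)
  out
}

#' @describeIn sewerseq-io Write named sequences to FASTA.
#' @param sequences Named character vector of DNA sequences.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' @describeIn sewerseq-io Read a reference database from FASTA whose
#'   description lines carry `source=<label>` and, for sewage-side records,
#'   `sewage_p95=<value>`.
#' @export
read_source_db <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  grab <- function(key) {
    m <- regmatches(headers, regexpr(paste0(key, "=[^ ]+"), headers))
    out <- rep(NA_character_, length(headers))
    hit <- grepl(paste0(key, "="), headers)
    out[hit] <- sub(paste0("^", key, "="), "", m)
    out
  }
  src <- grab("source")
  if (any(is.na(src))) {
    stop("every FASTA record needs a 'source=' tag in its description", call. = FALSE)
  }
  p95 <- suppressWarnings(as.numeric(grab("sewage_p95")))
  source_db(ids, as.character(ss), src, p95)
}

#' @describeIn sewerseq-io Write a reference database to FASTA with tagged
#'   description lines.
#' @param db A [source_db()].
#' @export
write_source_db <- function(db, path) {
  stopifnot(is_source_db(db))
  tag <- ifelse(is.na(db$sewage_p95), "",
                sprintf(" sewage_p95=%.10g", db$sewage_p95))
  headers <- sprintf("%s source=%s%s", db$reference_id, db$source, tag)
  seqs <- db$sequence
  names(seqs) <- headers
  write_fasta(seqs, path)
}

#' @describeIn sewerseq-io Read a sample metadata TSV.
#' @export
read_sample_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @describeIn sewerseq-io Read qPCR observations from CSV
#'   (columns `sample_id`, `cq` where non-detects are `"ND"`, optional
#'   `replicate`).
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cq") %in% colnames(df))) {
    stop("qPCR CSV needs 'sample_id' and 'cq' columns", call. = FALSE)
  }
  df
}

#' @describeIn sewerseq-io Read a simulation configuration from YAML; fields
#'   mirror the arguments of [synthetic_config()], with log-normal variables
#'   given as `{geometric_mean, geometric_sd}` pairs.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (field in c("sewage_fraction_spec", "c_sewage_hb_spec",
                  "c_sewage_cells_spec", "c_river_cells_spec")) {
    if (!is.null(raw[[field]])) {
      raw[[field]] <- lognormal_spec(raw[[field]]$geometric_mean,
                                     raw[[field]]$geometric_sd)
    }
  }
  do.call(synthetic_config, raw)
}

#' Write a synthetic study bundle to a directory of plain-text files
#'
#' Emits counts (`counts.tsv`), ASV sequences (`asvs.fasta`), the three
#' reference databases (`freshwater.fasta`, `sewer.fasta`, `stool.fasta`),
#' sample metadata (`metadata.tsv`), qPCR observations (`qpcr.csv`) and
#' ground truth (`ground_truth.json`).
#'
#' @param bundle Result of [simulate_pollution_study()].
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_asv_counts(bundle$table$counts, file.path(dir, "counts.tsv"))
  write_fasta(bundle$table$sequences, file.path(dir, "asvs.fasta"))
  write_source_db(bundle$databases$freshwater, file.path(dir, "freshwater.fasta"))
  write_source_db(bundle$databases$sewer, file.path(dir, "sewer.fasta"))
  write_source_db(bundle$databases$human_stool, file.path(dir, "stool.fasta"))
  utils::write.table(bundle$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(bundle$hb, file.path(dir, "qpcr.csv"), row.names = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(
    list(f = as.list(truth$f), asv_source = as.list(truth$asv_source),
         r_true = as.list(truth$r_true), hb_true = as.list(truth$hb_true)),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
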