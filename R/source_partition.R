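#' Percentile of an ASV's relative abundance across river samples
#'
#' Computes the `q`-th percentile of an ASV's per-sample relative abundances
#' across all river samples with nonzero read totals. Samples where the ASV
#' is absent contribute zeros — they are observations, not missing values.
#' The percentile is computed by linear interpolation between closest order
#' statistics (the inclusive convention, `stats::quantile` type 7); the
#' convention is recorded by [partition_sources()] so results are auditable.
#'
#' @param asv ASV id present in `table`.
#' @param table An [asv_table()].
#' @param q Percentile in `[0, 100]`; the inclusion filter uses `q = 5`.
#' @return Scalar relative abundance.
#' @export
river_percentile <- function(asv, table, q = 5) {
  stopifnot(is_asv_table(table))
  if (!asv %in% asv_ids(table)) stop("unknown ASV id: ", asv, call. = FALSE)
  ra <- relative_abundance(table)[, asv]
  ra <- ra[!is.na(ra)]
  if (!length(ra)) stop("no river samples with nonzero totals", call. = FALSE)
  unname(stats::quantile(ra, probs = q / 100, type = 7))
}

#' Inclusion filter for sewage-side matches
#'
#' An ASV that matches a sewer or human-stool reference is admitted to that
#' category only if its 5th-percentile relative abundance across river
#' samples is strictly lower than the reference's 95th-percentile relative
#' abundance in raw sewage. An ASV more abundant in rivers than it ever
#' plausibly is in sewage is unlikely to be sewage-derived, whatever its
#' sequence says.
#'
#' @param river_p5 5th-percentile relative abundance in river samples.
#' @param sewage_p95 95th-percentile relative abundance in reference sewage.
#' @return `TRUE` iff `river_p5 < sewage_p95` (strict).
#' @export
sewage_inclusion_filter <- function(river_p5, sewage_p95) {
  if (any(is.na(sewage_p95))) {
    stop("'sewage_p95' is required for the inclusion filter", call. = FALSE)
  }
  river_p5 < sewage_p95
}

#' Partition ASVs into source categories
#'
#' Assigns every ASV in the table to exactly one of `freshwater`,
#' `human_fecal`, `sewer`, or `uncategorized` by exact full-length sequence
#' matching with the precedence order freshwater, then human stool, then
#' sewer. Freshwater matches are final: an ASV matching both a freshwater
#' and a sewage-side reference is freshwater (the freshwater assignment
#' excludes it from the sewage categories). A sewage-side match is admitted
#' only if it passes [sewage_inclusion_filter()]; otherwise the ASV falls to
#' `uncategorized`, as do ASVs matching no database.
#'
#' Freshwater membership may alternatively be supplied directly as a per-ASV
#' logical vector `freshwater_flags` (emulating an upstream taxonomy-based
#' assignment); flagged ASVs are treated exactly like freshwater sequence
#' matches and feed the same precedence logic.
#'
#' @param table An [asv_table()]; duplicate ASV sequences are rejected
#'   (upstream dereplication is assumed).
#' @param freshwater_db,sewer_db,stool_db [source_db()] objects.
#' @param apply_filter Apply the percentile inclusion filter (default TRUE);
#'   `FALSE` admits every sewage-side match (a permissive mode for
#'   validation against known ground truth).
#' @param river_q Percentile used on the river side (default 5).
#' @param freshwater_flags Optional named logical vector over ASV ids.
#' @return A data frame of class `partition_result` with columns `asv_id`,
#'   `category`, `reference_id` (`NA` when unmatched), `river_p5` (`NA` for
#'   ASVs never tested against the filter); attributes record the quantile
#'   convention and filter settings.
#' @export
partition_sources <- function(table, freshwater_db, sewer_db, stool_db,
                              apply_filter = TRUE, river_q = 5,
                              freshwater_flags = NULL) {
  stopifnot(is_asv_table(table), is_source_db(freshwater_db),
            is_source_db(sewer_db), is_source_db(stool_db))
  if (anyDuplicated(table$sequences)) {
    stop("duplicate ASV sequences in the table; dereplicate upstream", call. = FALSE)
  }
  ids <- asv_ids(table)
  seqs <- table$sequences
  fw_ref <- exact_match(seqs, freshwater_db)
  if (!is.null(freshwater_flags)) {
    flagged <- names(freshwater_flags)[freshwater_flags]
    flagged <- intersect(flagged, ids)
    fw_ref[match(flagged, ids)] <- ifelse(
      is.na(fw_ref[match(flagged, ids)]), "flagged", fw_ref[match(flagged, ids)])
  }
  st_ref <- exact_match(seqs, stool_db)
  sw_ref <- exact_match(seqs, sewer_db)

  ra <- relative_abundance(table)
  ra <- ra[stats::complete.cases(ra), , drop = FALSE]
  if (!nrow(ra)) stop("no samples with nonzero totals", call. = FALSE)
  p5_all <- apply(ra, 2, stats::quantile, probs = river_q / 100, type = 7)

  category <- rep("uncategorized", length(ids))
  reference_id <- rep(NA_character_, length(ids))
  river_p5 <- rep(NA_real_, length(ids))

  take_sewage <- function(refv, db, cat_label, remaining) {
    hit <- remaining & !is.na(refv)
    for (i in which(hit)) {
      p95 <- db$sewage_p95[match(refv[i], db$reference_id)]
      river_p5[i] <<- unname(p5_all[ids[i]])
      pass <- if (apply_filter) sewage_inclusion_filter(river_p5[i], p95) else TRUE
      if (pass) {
        category[i] <<- cat_label
        reference_id[i] <<- refv[i]
      }
    }
    remaining & is.na(refv)
  }

  is_fw <- !is.na(fw_ref)
  category[is_fw] <- "freshwater"
  reference_id[is_fw] <- fw_ref[is_fw]
  remaining <- !is_fw
  remaining <- take_sewage(st_ref, stool_db, "human_fecal", remaining)
  take_sewage(sw_ref, sewer_db, "sewer", remaining)

  out <- data.frame(asv_id = ids, category = category,
                    reference_id = reference_id, river_p5 = river_p5,
                    stringsAsFactors = FALSE)
  attr(out, "quantile_type") <- 7L
  attr(out, "river_q") <- river_q
  attr(out, "filter_applied") <- apply_filter
  attr(out, "zeros_included") <- TRUE
  class(out) <- c("partition_result", "data.frame")
  out
}

partition_categories <- c("freshwater", "human_fecal", "sewer", "uncategorized")

#' Per-sample relative abundance of each source category
#'
#' Sums member-ASV relative abundances within each of the four source
#' categories, per sample (the per-sample stacked-bar summary of a source
#' partition). Proportions sum to 1 for samples with reads; samples with
#' zero total reads are reported as `NA`.
#'
#' @param table An [asv_table()].
#' @param partition A `partition_result` covering all ASVs of `table`.
#' @return Matrix samples x 4 (`freshwater`, `human_fecal`, `sewer`,
#'   `uncategorized`).
#' @export
category_relative_abundance <- function(table, partition) {
  stopifnot(is_asv_table(table), inherits(partition, "partition_result"))
  if (!setequal(partition$asv_id, asv_ids(table))) {
    stop("partition does not cover the table's ASVs", call. = FALSE)
  }
  ra <- relative_abundance(table)
  cat_of <- partition$category[match(asv_ids(table), partition$asv_id)]
  out <- vapply(partition_categories, function(k) {
    cols <- which(cat_of == k)
    if (!length(cols)) rep(0, nrow(ra)) else rowSums(ra[, cols, drop = FALSE])
  }, numeric(nrow(ra)))
  out <- matrix(out, nrow = nrow(ra),
                dimnames = list(sample_ids(table), partition_categories))
  out[is.na(rowSums(out)), ] <- NA_real_
  out
}

#' Per-sample sewage-sequence proportion
#'
#' The combined sewer + human-fecal relative abundance per sample: the
#' quantity compared against the sequence-abundance risk threshold. The
#' human-fecal component can be excluded to report the sewer-only
#' proportion.
#'
#' @param table An [asv_table()].
#' @param partition A `partition_result`.
#' @param include_human_fecal Include the human-fecal category (default TRUE).
#' @return Named numeric vector in `[0, 1]` per sample (`NA` for zero-total
#'   samples).
#' @export
sewage_proportion <- function(table, partition, include_human_fecal = TRUE) {
  cra <- category_relative_abundance(table, partition)
  out <- cra[, "sewer"] + if (include_human_fecal) cra[, "human_fecal"] else 0
  stats::setNames(as.numeric(out), rownames(cra))
}
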