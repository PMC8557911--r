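#' Indicator-value specificity of ASVs for sample groups
#'
#' The specificity (positive predictive) component `A` of the
#' indicator-value framework: for an ASV and a group, the ASV's mean
#' relative abundance within the group divided by the sum of its group mean
#' abundances over all groups. Group means (rather than pooled sums) make
#' the statistic robust to unbalanced group sizes (the group-size-corrected
#' "IndVal.g" convention); set `mode = "pooled"` for the pooled-sum
#' alternative. An ASV absent from every retained sample scores 0 in every
#' group.
#'
#' @param table An [asv_table()].
#' @param grouping Named character/factor vector: group label per sample id.
#'   Samples of `table` absent from `grouping` are dropped (a restriction
#'   mask, e.g. urban samples only, is expressed by subsetting `grouping`).
#' @param mode `"group_mean"` (default) or `"pooled"`.
#' @return Matrix ASVs x groups of specificities in `[0, 1]`; rows of ASVs
#'   present anywhere sum to 1.
#' @export
indicator_specificity <- function(table, grouping,
                                  mode = c("group_mean", "pooled")) {
  mode <- match.arg(mode)
  g <- align_grouping(table, grouping)
  ra <- relative_abundance(table)[names(g), , drop = FALSE]
  groups <- levels(g)
  stat <- sapply(groups, function(k) {
    rows <- which(g == k)
    if (mode == "group_mean") {
      colMeans(ra[rows, , drop = FALSE])
    } else {
      colSums(ra[rows, , drop = FALSE])
    }
  })
  if (is.null(dim(stat))) stat <- matrix(stat, nrow = 1, dimnames = list(asv_ids(table), groups))
  tot <- rowSums(stat)
  out <- stat / ifelse(tot > 0, tot, 1)
  out[tot == 0, ] <- 0
  out
}

#' Indicator-value sensitivity of ASVs for sample groups
#'
#' The fidelity component `B`: the fraction of the group's samples in which
#' the ASV is detected (count > 0). Presence-based, hence invariant to any
#' abundance rescaling.
#'
#' @inheritParams indicator_specificity
#' @return Matrix ASVs x groups of sensitivities in `[0, 1]`.
#' @export
indicator_sensitivity <- function(table, grouping) {
  g <- align_grouping(table, grouping)
  cnt <- table$counts[names(g), , drop = FALSE]
  groups <- levels(g)
  out <- sapply(groups, function(k) {
    rows <- which(g == k)
    colMeans(cnt[rows, , drop = FALSE] > 0)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(asv_ids(table), groups))
  out
}

# validate and align a grouping vector to the table's samples
align_grouping <- function(table, grouping) {
  stopifnot(is_asv_table(table))
  if (is.null(names(grouping))) stop("'grouping' must be named by sample id", call. = FALSE)
  keep <- intersect(sample_ids(table), names(grouping))
  if (!length(keep)) stop("no samples shared between table and grouping", call. = FALSE)
  g <- grouping[keep]
  if (any(is.na(g))) stop("grouping labels must not be NA", call. = FALSE)
  g <- stats::setNames(factor(as.character(g)), keep)
  g <- droplevels(g)
  if (nlevels(g) < 2L) {
    stop("need >= 2 groups with samples after restriction", call. = FALSE)
  }
  g
}

#' Find ASVs strongly associated with sample groups
#'
#' Scores every ASV against every group by specificity and sensitivity, keeps
#' each ASV's best group (maximum specificity x sensitivity product), and
#' flags ASVs as strong indicators when both components meet their minimum
#' (both `>= 0.8` by default, the inclusive form of the 80% rule). Typical
#' use groups samples by HB contamination category, restricted to urban
#' samples, run separately on the sewage-side and freshwater communities
#' via `asv_subset`.
#'
#' @inheritParams indicator_specificity
#' @param min_spec,min_sens Inclusive thresholds for the strong flag.
#' @param asv_subset Optional character vector of ASV ids to score (e.g. the
#'   sewer + human-fecal members of a partition).
#' @param mode Specificity mode, see [indicator_specificity()].
#' @return Data frame `asv_id`, `group`, `specificity`, `sensitivity`,
#'   `strong`, with strong indicators first, sorted by group then descending
#'   score.
#' @export
find_indicators <- function(table, grouping, min_spec = 0.8, min_sens = 0.8,
                            asv_subset = NULL,
                            mode = c("group_mean", "pooled")) {
  mode <- match.arg(mode)
  A <- indicator_specificity(table, grouping, mode)
  B <- indicator_sensitivity(table, grouping)
  ids <- rownames(A)
  if (!is.null(asv_subset)) {
    ids <- intersect(ids, asv_subset)
    if (!length(ids)) stop("'asv_subset' matches no ASV in the table", call. = FALSE)
    A <- A[ids, , drop = FALSE]
    B <- B[ids, , drop = FALSE]
  }
  score <- A * B
  best <- max.col(score, ties.method = "first")
  out <- data.frame(
    asv_id = ids,
    group = colnames(A)[best],
    specificity = A[cbind(seq_along(ids), best)],
    sensitivity = B[cbind(seq_along(ids), best)],
    stringsAsFactors = FALSE
  )
  out$strong <- out$specificity >= min_spec & out$sensitivity >= min_sens
  out <- out[order(!out$strong, out$group,
                   -(out$specificity * out$sensitivity)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
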