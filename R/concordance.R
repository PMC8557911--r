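#' Classify samples against the dual pollution thresholds
#'
#' Places each sample in one of four quadrants by whether it exceeds the HB
#' concentration threshold and/or the sewage-sequence proportion threshold.
#' HB exceedance requires a quantified value at or above `hb_threshold`
#' (non-detects and detected-but-unquantifiable results never exceed);
#' sequence exceedance is `seq_proportion >= seq_threshold`, inclusive to
#' mirror the HB side.
#'
#' @param hb HB result data frame (columns `cn_per_100ml`, `censor`; e.g.
#'   from [process_qpcr()]), one row per sample.
#' @param seq_proportion Numeric vector in `[0, 1]`, same order as `hb`.
#' @param hb_threshold HB risk concentration (default 7800 CN/100 ml).
#' @param seq_threshold Sequence-proportion threshold (default 0.18).
#' @return Factor with levels `below_both`, `hb_only`, `seq_only`,
#'   `above_both`.
#' @export
classify_quadrant <- function(hb, seq_proportion, hb_threshold = 7800,
                              seq_threshold = 0.18) {
  stopifnot(is.data.frame(hb), all(c("cn_per_100ml", "censor") %in% names(hb)))
  if (length(seq_proportion) != nrow(hb)) {
    stop("one sequence proportion per HB result required", call. = FALSE)
  }
  if (any(is.na(seq_proportion))) {
    stop("missing sequence proportions", call. = FALSE)
  }
  if (any(seq_proportion < 0 | seq_proportion > 1)) {
    stop("sequence proportions must lie in [0, 1]", call. = FALSE)
  }
  if (!is_scalar_number(hb_threshold) || hb_threshold <= 0) {
    stop("'hb_threshold' must be positive", call. = FALSE)
  }
  if (!is_scalar_number(seq_threshold) || seq_threshold <= 0 || seq_threshold >= 1) {
    stop("'seq_threshold' must lie in (0, 1)", call. = FALSE)
  }
  exceeds_hb <- hb$censor == "quantified" &
    !is.na(hb$cn_per_100ml) & hb$cn_per_100ml >= hb_threshold
  exceeds_seq <- seq_proportion >= seq_threshold
  q <- ifelse(exceeds_hb & exceeds_seq, "above_both",
              ifelse(exceeds_hb, "hb_only",
                     ifelse(exceeds_seq, "seq_only", "below_both")))
  factor(q, levels = c("below_both", "hb_only", "seq_only", "above_both"))
}

#' Tabulate dual-threshold concordance
#'
#' Counts samples per quadrant and reports the agreement fraction (samples
#' below both thresholds plus samples above both).
#'
#' @param quadrants Factor from [classify_quadrant()].
#' @return List of class `concordance_counts`: `below_both`, `hb_only`,
#'   `seq_only`, `above_both`, `n_total`, `agreement` (count), and
#'   `agreement_fraction`.
#' @export
concordance_table <- function(quadrants) {
  if (!length(quadrants)) stop("no samples", call. = FALSE)
  quadrants <- factor(quadrants,
                      levels = c("below_both", "hb_only", "seq_only", "above_both"))
  tab <- table(quadrants)
  out <- list(
    below_both = unname(tab[["below_both"]]),
    hb_only = unname(tab[["hb_only"]]),
    seq_only = unname(tab[["seq_only"]]),
    above_both = unname(tab[["above_both"]]),
    n_total = length(quadrants)
  )
  out$agreement <- out$below_both + out$above_both
  out$agreement_fraction <- out$agreement / out$n_total
  class(out) <- "concordance_counts"
  out
}

#' @export
print.concordance_counts <- function(x, ...) {
  cat(sprintf(
    "dual-threshold concordance (n = %d): %d below both, %d HB only, %d sequence only, %d above both; agreement %d/%d (%.1f%%)\n",
    x$n_total, x$below_both, x$hb_only, x$seq_only, x$above_both,
    x$agreement, x$n_total, 100 * x$agreement_fraction))
  invisible(x)
}
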