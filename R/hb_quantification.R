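#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle (Cq) on log10 copies per
#' reaction across a dilution series. Amplification efficiency is derived
#' from the slope as `10^(-1/slope) - 1` (a slope of -3.322 is perfect
#' doubling, efficiency 1); a warning is issued when efficiency falls
#' outside the conventional 90-110% acceptance window.
#'
#' @param log10_cn log10 copy number per reaction for each standard point.
#' @param cq Measured Cq values, same length.
#' @return Object of class `standard_curve`: `slope` (Cq per log10 CN,
#'   negative for a valid curve), `intercept` (Cq at 1 CN), `r_squared`,
#'   `efficiency`, `n_points`.
#' @examples
#' pts <- data.frame(log10_cn = 1:5, cq = 38 - 3.368 * (1:5))
#' fit_standard_curve(pts$log10_cn, pts$cq)$efficiency  # ~0.981
#' @export
fit_standard_curve <- function(log10_cn, cq) {
  if (length(log10_cn) != length(cq)) stop("length mismatch", call. = FALSE)
  if (any(!is.finite(log10_cn)) || any(!is.finite(cq))) {
    stop("standard points must be finite", call. = FALSE)
  }
  if (length(unique(log10_cn)) < 3L) {
    stop("need >= 3 distinct dilution levels", call. = FALSE)
  }
  fit <- stats::lm(cq ~ log10_cn)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) {
    stop("standard-curve slope must be negative (Cq decreases with template)",
         call. = FALSE)
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cq - mean(cq))^2)
  efficiency <- 10^(-1 / slope) - 1
  if (efficiency < 0.9 || efficiency > 1.1) {
    warning(sprintf("assay efficiency %.1f%% outside the 90-110%% window",
                    100 * efficiency), call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         efficiency = efficiency, n_points = length(cq)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: Cq = %.4f %+.4f log10(CN); E = %.1f%%, R2 = %.4f\n",
              x$intercept, x$slope, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' Volume conversion constants for reporting qPCR results per 100 ml
#'
#' Converts copies per reaction to copies per 100 ml of original water
#' sample: `CN/100ml = CN/reaction * extract_to_reactions *
#' (reporting_basis_ml / volume_filtered_ml)`. Defaults (250 ml filtered,
#' 30 reaction-equivalents per extract, 100 ml basis) give a factor of 12,
#' so the lowest quantifiable standard of 15 CN/reaction corresponds to an
#' LOQ of 180 CN/100 ml. The per-step elution and template volumes behind
#' `extract_to_reactions` are assay-specific; only their aggregate matters
#' here and it is a configuration field, never hard-coded.
#'
#' @param volume_filtered_ml Water volume filtered per sample (ml).
#' @param extract_to_reactions Reaction-equivalents per filter extract.
#' @param reporting_basis_ml Reporting basis (ml), conventionally 100.
#' @return Object of class `conversion_constants` with the derived `factor`.
#' @export
conversion_constants <- function(volume_filtered_ml = 250,
                                 extract_to_reactions = 30,
                                 reporting_basis_ml = 100) {
  for (nm in c("volume_filtered_ml", "extract_to_reactions", "reporting_basis_ml")) {
    stop_if_not_scalar(get(nm), nm, positive = TRUE)
  }
  structure(
    list(volume_filtered_ml = volume_filtered_ml,
         extract_to_reactions = extract_to_reactions,
         reporting_basis_ml = reporting_basis_ml,
         factor = extract_to_reactions * reporting_basis_ml / volume_filtered_ml),
    class = "conversion_constants"
  )
}

#' Convert Cq values to marker concentrations in CN/100 ml
#'
#' Inverts the standard curve (`CN/reaction = 10^((Cq - intercept)/slope)`)
#' and applies the volume conversion. Non-detects (`NA` or `"ND"`) carry no
#' numeric value and are flagged `nondetect`; no zero is substituted, and
#' downstream arithmetic on them errors rather than silently imputing.
#'
#' @param cq Numeric or character vector; `NA` or `"ND"` mark non-detects.
#' @param curve A [fit_standard_curve()] result.
#' @param constants A [conversion_constants()].
#' @return Data frame: `cn_per_reaction`, `cn_per_100ml` (both `NA` for
#'   non-detects), `censor` (`nondetect` or `quantified`; the `below_loq`
#'   refinement is applied by [categorize_hb()]).
#' @export
quantify_hb <- function(cq, curve, constants = conversion_constants()) {
  stopifnot(inherits(curve, "standard_curve"),
            inherits(constants, "conversion_constants"))
  if (is.character(cq)) {
    nd <- toupper(trimws(cq)) %in% c("ND", "NA", "")
    vals <- suppressWarnings(as.numeric(cq))
    if (any(!nd & is.na(vals))) stop("malformed Cq values", call. = FALSE)
    vals[nd] <- NA_real_
    cq <- vals
  }
  nd <- is.na(cq)
  cn_rxn <- 10^((cq - curve$intercept) / curve$slope)
  cn_100ml <- cn_rxn * constants$factor
  data.frame(
    cn_per_reaction = cn_rxn,
    cn_per_100ml = cn_100ml,
    censor = ifelse(nd, "nondetect", "quantified"),
    stringsAsFactors = FALSE
  )
}

# inverse transform, used for round-trip validation
cq_from_cn <- function(cn_per_reaction, curve) {
  curve$intercept + curve$slope * log10(cn_per_reaction)
}

# vectorized four-way categorization shared with the synthetic generator
hb_category <- function(cn_per_100ml, censor, loq_cn_100ml = 180,
                        risk_cn_100ml = 7800) {
  ifelse(censor == "nondetect", "undetectable",
         ifelse(censor == "below_loq" | cn_per_100ml < loq_cn_100ml,
                "unquantifiable",
                ifelse(cn_per_100ml >= risk_cn_100ml, "risk", "quantifiable")))
}

#' Categorize HB results into the four contamination levels
#'
#' Samples are classed as `undetectable` (non-detect), `unquantifiable`
#' (detected but below the limit of quantification), `quantifiable`
#' (`loq <= cn < risk`), or `risk` (`cn >= risk`, boundary inclusive). The
#' LOQ boundary itself is quantifiable.
#'
#' @param hb Data frame from [quantify_hb()] (columns `cn_per_100ml`,
#'   `censor`).
#' @param loq_cn_100ml Limit of quantification (default 180 CN/100 ml).
#' @param risk_cn_100ml Risk threshold (default 7800 CN/100 ml, the
#'   concentration associated with an excess illness risk of 0.03).
#' @return `hb` with `censor` refined (`below_loq` for detected values under
#'   the LOQ) and a `category` column added.
#' @export
categorize_hb <- function(hb, loq_cn_100ml = 180, risk_cn_100ml = 7800) {
  stopifnot(is.data.frame(hb), all(c("cn_per_100ml", "censor") %in% names(hb)))
  detected <- hb$censor != "nondetect"
  hb$censor[detected & hb$cn_per_100ml < loq_cn_100ml] <- "below_loq"
  hb$category <- hb_category(hb$cn_per_100ml, hb$censor,
                             loq_cn_100ml, risk_cn_100ml)
  hb
}

#' Process a qPCR observation table into HB results
#'
#' Averages replicate Cq values per sample on the Cq scale (a sample is a
#' non-detect only when every replicate is), quantifies against the standard
#' curve, and categorizes.
#'
#' @param qpcr Data frame with `sample_id`, `cq` (numeric or `"ND"`),
#'   optional `replicate`.
#' @param curve A [fit_standard_curve()] result.
#' @param constants A [conversion_constants()].
#' @param loq_cn_100ml,risk_cn_100ml Passed to [categorize_hb()].
#' @return Data frame: `sample_id`, `cn_per_100ml`, `censor`, `category`.
#' @export
process_qpcr <- function(qpcr, curve, constants = conversion_constants(),
                         loq_cn_100ml = 180, risk_cn_100ml = 7800) {
  stopifnot(all(c("sample_id", "cq") %in% names(qpcr)))
  cqv <- qpcr$cq
  if (is.character(cqv)) {
    nd <- toupper(trimws(cqv)) %in% c("ND", "NA", "")
    cqv <- suppressWarnings(as.numeric(cqv))
    if (any(!nd & is.na(cqv))) stop("malformed Cq values", call. = FALSE)
  }
  mean_cq <- tapply(cqv, qpcr$sample_id, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  res <- quantify_hb(as.numeric(mean_cq), curve, constants)
  res <- categorize_hb(res, loq_cn_100ml, risk_cn_100ml)
  data.frame(sample_id = names(mean_cq),
             cn_per_100ml = res$cn_per_100ml,
             censor = res$censor,
             category = res$category,
             stringsAsFactors = FALSE, row.names = NULL)
}
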