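#' Volumetric sewage fraction from HB concentrations
#'
#' The volumetric fraction of sewage in river water, `f`, follows from a
#' simple mass balance on the human Bacteroides (HB) marker: the marker
#' copies found in a river volume are attributed entirely to the sewage
#' fraction of that volume, so
#' \deqn{f = C_{river,HB} / C_{sewage,HB}.}
#'
#' @param c_river_hb HB concentration in the river (CN/100 ml), `>= 0`.
#' @param c_sewage_hb HB concentration in raw sewage (CN/100 ml), `> 0`.
#' @return Numeric vector `f`. Values at or above 1 (river apparently at
#'   least as concentrated as sewage) are returned with a warning: they
#'   indicate a misconfigured input rather than a physical mixture.
#' @examples
#' sewage_fraction(7800, 7.8e6)  # 0.001
#' @export
sewage_fraction <- function(c_river_hb, c_sewage_hb) {
  if (any(!is.finite(c_sewage_hb)) || any(c_sewage_hb <= 0)) {
    stop("'c_sewage_hb' must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(c_river_hb)) || any(c_river_hb < 0)) {
    stop("'c_river_hb' must be nonnegative", call. = FALSE)
  }
  f <- c_river_hb / c_sewage_hb
  if (any(f >= 1)) {
    warning("f >= 1: river HB concentration reaches or exceeds the sewage HB concentration",
            call. = FALSE)
  }
  f
}

#' Sewage-sequence relative abundance from the volumetric fraction
#'
#' Converts a volumetric sewage fraction `f` into the expected relative
#' abundance `r` of sewage-derived sequences in an amplicon library, using
#' the total cell concentrations of sewage and river water. Two algebraic
#' forms are provided:
#'
#' * `"ratio"`: \deqn{r = \frac{C_{sewage,cells} \cdot f}{C_{river,cells} \cdot (1-f)}}
#'   the sewage-to-river cell ratio. For small `f` this approximates the
#'   sequence proportion; it can exceed 1.
#' * `"composition"`: \deqn{r = \frac{C_{sewage,cells} \cdot f}{C_{sewage,cells} \cdot f + C_{river,cells} \cdot (1-f)}}
#'   the exact mixture proportion, guaranteed in \[0, 1\] and always
#'   `<=` the ratio form.
#'
#' Both assume the relative abundance of a sequence in the library reflects
#' its relative abundance among cells in the volume analysed.
#'
#' @param f Volumetric sewage fraction(s) in `[0, 1)`.
#' @param c_sewage_cells Total cell concentration in sewage (cells/100 ml), `> 0`.
#' @param c_river_cells Total cell concentration in river water (cells/100 ml), `> 0`.
#' @param variant `"ratio"` or `"composition"`.
#' @return Numeric vector `r`.
#' @examples
#' sewage_read_fraction(0.001, 1e9, 1e7, "ratio")        # ~0.1001
#' sewage_read_fraction(0.001, 1e9, 1e7, "composition")  # ~0.0910
#' @export
sewage_read_fraction <- function(f, c_sewage_cells, c_river_cells,
                                 variant = c("ratio", "composition")) {
  variant <- match.arg(variant)
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1)) {
    stop("'f' must lie in [0, 1)", call. = FALSE)
  }
  if (any(c_sewage_cells <= 0) || any(c_river_cells <= 0)) {
    stop("cell concentrations must be strictly positive", call. = FALSE)
  }
  num <- c_sewage_cells * f
  den <- c_river_cells * (1 - f)
  switch(variant,
    ratio = num / den,
    composition = num / (num + den)
  )
}

#' Monte Carlo configuration for the sequence-abundance risk threshold
#'
#' Bundles the inputs of the mass-balance Monte Carlo: the fixed river HB
#' concentration (set at the health-risk threshold), and log-normal
#' distributions for sewage HB concentration and the two total cell
#' concentrations.
#'
#' @param c_river_hb Fixed river HB concentration (CN/100 ml); default 7800,
#'   the concentration associated with an excess illness risk of 0.03.
#' @param c_sewage_hb,c_sewage_cells,c_river_cells [lognormal_spec()] objects
#'   (CN/100 ml and cells/100 ml respectively).
#' @param n_draws Number of Monte Carlo draws, `>= 1000`.
#' @param seed Integer RNG seed.
#' @param variant Formula variant passed to [sewage_read_fraction()].
#' @param summary Central-estimate statistic: geometric mean (default; equals
#'   the median under log-normality), median, or arithmetic mean.
#' @return An object of class `mc_config`.
#' @export
monte_carlo_config <- function(c_river_hb = 7800,
                               c_sewage_hb,
                               c_sewage_cells,
                               c_river_cells,
                               n_draws = 100000L,
                               seed = 1L,
                               variant = c("ratio", "composition"),
                               summary = c("geometric_mean", "median",
                                           "arithmetic_mean")) {
  stop_if_not_scalar(c_river_hb, "c_river_hb", positive = TRUE)
  stopifnot(is_lognormal_spec(c_sewage_hb),
            is_lognormal_spec(c_sewage_cells),
            is_lognormal_spec(c_river_cells))
  if (!is_scalar_number(n_draws) || n_draws < 1000) {
    stop("'n_draws' must be >= 1000", call. = FALSE)
  }
  structure(
    list(c_river_hb = c_river_hb,
         c_sewage_hb = c_sewage_hb,
         c_sewage_cells = c_sewage_cells,
         c_river_cells = c_river_cells,
         n_draws = as.integer(n_draws),
         seed = as.integer(seed),
         variant = match.arg(variant),
         summary = match.arg(summary)),
    class = "mc_config"
  )
}

#' Example threshold configuration
#'
#' A documented, literature-plausible parameterisation for deriving the
#' sewage-sequence risk threshold: sewage HB at geometric mean 7.8e6
#' CN/100 ml (so `f` at the risk concentration centres on 0.001) with GSD 3;
#' sewage total cells at 1.8e10 cells/100 ml (about 1.8e8 cells/ml of raw
#' sewage) with GSD 2; river total cells at 1e8 cells/100 ml (1e6 cells/ml)
#' with GSD 7, river-cell variability being the dominant error source.
#' These are illustrative defaults for the example workflow, not fitted
#' study-specific values; substitute your own measured distributions for a
#' site-specific threshold.
#'
#' @param n_draws,seed Passed to [monte_carlo_config()].
#' @return An `mc_config`.
#' @export
example_threshold_config <- function(n_draws = 100000L, seed = 1L) {
  monte_carlo_config(
    c_river_hb = 7800,
    c_sewage_hb = lognormal_spec(7.8e6, 3),
    c_sewage_cells = lognormal_spec(1.8e10, 2),
    c_river_cells = lognormal_spec(1e8, 7),
    n_draws = n_draws,
    seed = seed
  )
}

new_threshold_estimate <- function(r_central, r_gsd, n_draws, n_rejected,
                                   variant, summary, method, draws = NULL) {
  structure(
    list(r_central = r_central,
         r_gsd = r_gsd,
         interval_lo = r_central / r_gsd,
         interval_hi = r_central * r_gsd,
         n_draws = n_draws,
         n_rejected = n_rejected,
         variant = variant,
         summary = summary,
         method = method,
         draws = draws),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "sewage-sequence threshold (%s, %s): %.3g (+/-1 GSD: %.3g to %.3g), GSD %.3g\n",
    x$method, x$variant, x$r_central, x$interval_lo, x$interval_hi, x$r_gsd))
  invisible(x)
}

#' Monte Carlo derivation of the sewage-sequence risk threshold
#'
#' Draws the three log-normal inputs independently `n_draws` times, computes
#' the volumetric fraction `f` and then the sequence relative abundance `r`
#' per draw, and summarises the distribution of `r` by its central estimate
#' and geometric standard deviation. Draws with `f >= 1` (sewage HB drawn
#' below the river threshold) are physically meaningless and are rejected,
#' not clamped; their count is reported, and more than 10% rejections aborts
#' as a misconfiguration.
#'
#' @param config An [monte_carlo_config()].
#' @param keep_draws Retain the vector of simulated `r` values in the result.
#' @return A `threshold_estimate`: central estimate, geometric SD, and the
#'   `central / gsd` to `central * gsd` interval. Deterministic given the
#'   config seed.
#' @seealso [analytic_threshold()] for the closed-form small-`f` oracle.
#' @export
run_monte_carlo <- function(config, keep_draws = FALSE) {
  stopifnot(inherits(config, "mc_config"))
  with_seed(config$seed, {
    shb <- draw_lognormal(config$c_sewage_hb, config$n_draws)
    scells <- draw_lognormal(config$c_sewage_cells, config$n_draws)
    rcells <- draw_lognormal(config$c_river_cells, config$n_draws)
    f <- config$c_river_hb / shb
    ok <- f < 1
    n_rejected <- sum(!ok)
    if (n_rejected > 0.1 * config$n_draws) {
      stop(sprintf(
        "%d of %d draws gave f >= 1; sewage HB distribution inconsistent with the river threshold",
        n_rejected, config$n_draws), call. = FALSE)
    }
    r <- sewage_read_fraction(f[ok], scells[ok], rcells[ok], config$variant)
    lr <- log(r)
    central <- switch(config$summary,
      geometric_mean = exp(mean(lr)),
      median = stats::median(r),
      arithmetic_mean = mean(r)
    )
    gsd <- if (length(r) > 1) exp(stats::sd(lr)) else 1
    new_threshold_estimate(central, gsd, length(r), n_rejected,
                           config$variant, config$summary, "monte_carlo",
                           draws = if (keep_draws) r else NULL)
  })
}

#' Analytic small-fraction threshold (log-normal oracle)
#'
#' Closed-form counterpart of [run_monte_carlo()] valid when `f` is small:
#' with `1 - f` treated as 1, `log r` is the sum of independent normals,
#' \deqn{\ln r = \ln C_{sewage,cells} - \ln C_{river,cells} + \ln C_{river,HB} - \ln C_{sewage,HB},}
#' so `r` is exactly log-normal with geometric mean
#' `exp(mu_scells - mu_rcells + log(c_river_hb) - mu_shb)` and geometric SD
#' `exp(sqrt(sigma_scells^2 + sigma_rcells^2 + sigma_shb^2))`. Used as the
#' independent validation oracle for the simulation.
#'
#' @param config An [monte_carlo_config()].
#' @return A `threshold_estimate` with `method = "analytic"`.
#' @export
analytic_threshold <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  mu <- config$c_sewage_cells$mu - config$c_river_cells$mu +
    log(config$c_river_hb) - config$c_sewage_hb$mu
  sigma <- sqrt(config$c_sewage_cells$sigma^2 +
                config$c_river_cells$sigma^2 +
                config$c_sewage_hb$sigma^2)
  new_threshold_estimate(exp(mu), exp(sigma), NA_integer_, 0L,
                         "ratio", "geometric_mean", "analytic")
}
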