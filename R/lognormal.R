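#' Log-normal distribution specification on the geometric scale
#'
#' Environmental concentrations (cells or marker copies per volume) are
#' conventionally summarised by a geometric mean and a geometric standard
#' deviation (GSD). A `lognormal_spec` stores that pair together with the
#' equivalent natural-log-scale parameters `mu = log(geometric_mean)` and
#' `sigma = log(geometric_sd)`; the conversion is exact and invertible.
#' A GSD of 1 denotes a degenerate (point-mass) distribution.
#'
#' @param geometric_mean Geometric mean in natural units; strictly positive.
#' @param geometric_sd Geometric standard deviation; dimensionless, `>= 1`.
#' @return An object of class `lognormal_spec`.
#' @examples
#' spec <- lognormal_spec(7.8e6, 3)
#' spec$mu     # log(7.8e6)
#' spec$sigma  # log(3)
#' @export
lognormal_spec <- function(geometric_mean, geometric_sd = 1) {
  stop_if_not_scalar(geometric_mean, "geometric_mean", positive = TRUE)
  stop_if_not_scalar(geometric_sd, "geometric_sd")
  if (geometric_sd < 1) {
    stop("'geometric_sd' must be >= 1 (1 means a point mass)", call. = FALSE)
  }
  structure(
    list(
      geometric_mean = geometric_mean,
      geometric_sd = geometric_sd,
      mu = log(geometric_mean),
      sigma = log(geometric_sd)
    ),
    class = "lognormal_spec"
  )
}

#' @export
print.lognormal_spec <- function(x, ...) {
  cat(sprintf("log-normal: geometric mean %.4g, geometric SD %.4g\n",
              x$geometric_mean, x$geometric_sd))
  invisible(x)
}

is_lognormal_spec <- function(x) inherits(x, "lognormal_spec")

is_degenerate <- function(spec) spec$sigma == 0

#' Draw from a log-normal specification
#'
#' @param spec A [lognormal_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`; a degenerate spec (GSD 1) returns the
#'   geometric mean repeated, without consuming random numbers.
#' @export
draw_lognormal <- function(spec, n) {
  stopifnot(is_lognormal_spec(spec))
  if (is_degenerate(spec)) {
    rep(spec$geometric_mean, n)
  } else {
    stats::rlnorm(n, meanlog = spec$mu, sdlog = spec$sigma)
  }
}

# quantile of the spec (used for truncation feasibility checks)
quantile_lognormal <- function(spec, p) {
  if (is_degenerate(spec)) rep(spec$geometric_mean, length(p))
  else stats::qlnorm(p, meanlog = spec$mu, sdlog = spec$sigma)
}
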