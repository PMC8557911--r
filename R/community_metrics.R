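#' Shannon diversity
#'
#' `H = -sum(p_i * log(p_i))` over taxa with `p_i > 0`, in nats by default
#' (natural log, the convention of standard community-ecology software);
#' the base is configurable.
#'
#' @param counts Nonnegative numeric vector of taxon counts (or a
#'   samples-by-taxa matrix, giving one value per row).
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index (vector for matrix input). Errors on an all-zero
#'   sample: its diversity is undefined.
#' @examples
#' shannon_diversity(c(25, 25, 25, 25))  # log(4)
#' @export
shannon_diversity <- function(counts, base = exp(1)) {
  if (is.matrix(counts)) {
    return(apply(counts, 1, shannon_diversity, base = base))
  }
  check_count_vector(counts)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Simpson diversity
#'
#' The complement form `1 - sum(p_i^2)` (probability that two reads drawn
#' without replacement-bias are different taxa); `inverse = TRUE` returns
#' the inverse form `1 / sum(p_i^2)` instead.
#'
#' @inheritParams shannon_diversity
#' @param inverse Return inverse Simpson instead of the complement.
#' @return Simpson index (vector for matrix input).
#' @examples
#' simpson_diversity(rep(10, 5))  # 1 - 1/5
#' @export
simpson_diversity <- function(counts, inverse = FALSE) {
  if (is.matrix(counts)) {
    return(apply(counts, 1, simpson_diversity, inverse = inverse))
  }
  check_count_vector(counts)
  p <- counts / sum(counts)
  d <- sum(p^2)
  if (inverse) 1 / d else 1 - d
}

check_count_vector <- function(counts) {
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be nonnegative and non-missing", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("all-zero sample: diversity undefined", call. = FALSE)
  }
  invisible(counts)
}

#' Per-sample alpha diversity summary
#'
#' @param table An [asv_table()].
#' @return Data frame: `sample_id`, `richness` (observed ASVs), `shannon`
#'   (nats), `simpson` (complement form). Zero-total samples are `NA`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(is_asv_table(table))
  cnt <- table$counts
  data.frame(
    sample_id = rownames(cnt),
    richness = rowSums(cnt > 0),
    shannon = apply(cnt, 1, function(x) if (sum(x) > 0) shannon_diversity(x) else NA_real_),
    simpson = apply(cnt, 1, function(x) if (sum(x) > 0) simpson_diversity(x) else NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`. With `relative = TRUE`
#' (default) each sample is first converted to relative abundances, so
#' unequal sequencing depths do not masquerade as community differences.
#' Given a matrix, returns the full pairwise dissimilarity matrix
#' (symmetric, zero diagonal, values in `[0, 1]`).
#'
#' @param x Nonnegative vector, or samples-by-taxa matrix if `y` is `NULL`.
#' @param y Optional second vector.
#' @param relative Normalise to relative abundances first.
#' @return Scalar for two vectors; square symmetric matrix for matrix input.
#' @examples
#' bray_curtis(c(0.7, 0.3, 0), c(0.4, 0.3, 0.3))  # 0.3
#' @export
bray_curtis <- function(x, y = NULL, relative = TRUE) {
  if (is.null(y)) {
    if (!is.matrix(x)) stop("matrix input required when 'y' is missing", call. = FALSE)
    n <- nrow(x)
    out <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        out[i, j] <- out[j, i] <- bray_curtis(x[i, ], x[j, ], relative = relative)
      }
    }
    return(out)
  }
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(x) + sum(y) == 0) stop("both samples empty: dissimilarity undefined", call. = FALSE)
  if (relative) {
    if (sum(x) == 0 || sum(y) == 0) {
      stop("zero-total sample: relative abundances undefined", call. = FALSE)
    }
    x <- x / sum(x)
    y <- y / sum(y)
  }
  sum(abs(x - y)) / sum(x + y)
}

# one-factor pseudo-F from a squared-dissimilarity matrix and a grouping
pseudo_f <- function(d2, g) {
  n <- nrow(d2)
  a <- nlevels(g)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (k in levels(g)) {
    idx <- which(g == k)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

# all permutations of the elements of v (v small), as a list
all_permutations <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- vector("list", factorial(n))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in all_permutations(v[-i])) {
      k <- k + 1L
      out[[k]] <- c(v[i], p)
    }
  }
  out
}

#' One-factor permutational multivariate ANOVA (PERMANOVA)
#'
#' Tests whether community dissimilarity differs among groups of samples by
#' partitioning the total sum of squared dissimilarities into among- and
#' within-group components and permuting group labels. The pseudo-F is
#' `(SS_among/(a-1)) / (SS_within/(N-a))`; the p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)` for random
#' permutations, or the exact proportion over all `N!` relabelings when
#' `exhaustive = TRUE` (feasible for small `N`; the identity is included).
#'
#' @param d Dissimilarity matrix (square symmetric, e.g. from
#'   [bray_curtis()]) or a `dist` object.
#' @param labels Group label per sample, `>= 2` groups with `>= 2` samples
#'   each.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exhaustive Enumerate all label permutations instead of sampling.
#' @return List of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `method`.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = 1,
                      exhaustive = FALSE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("'d' must be a square dissimilarity matrix", call. = FALSE)
  }
  n <- nrow(d)
  if (length(labels) != n) stop("one label per sample required", call. = FALSE)
  g <- factor(as.character(labels))
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  d2 <- d^2
  f_obs <- pseudo_f(d2, g)
  if (exhaustive) {
    if (n > 9L) stop("exhaustive enumeration limited to n <= 9", call. = FALSE)
    perms <- all_permutations(seq_len(n))
    f_perm <- vapply(perms, function(p) pseudo_f(d2, g[p]), numeric(1))
    p_value <- mean(f_perm >= f_obs - 1e-12)
    method <- "exhaustive"
    n_used <- length(perms)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        pseudo_f(d2, g[sample.int(n)])
      }, numeric(1))
    })
    p_value <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    method <- "sampled"
    n_used <- n_permutations
  }
  structure(
    list(pseudo_F = f_obs, p_value = p_value,
         n_permutations = n_used, method = method),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations): pseudo-F = %.4f, p = %.4g\n",
              x$method, x$n_permutations, x$pseudo_F, x$p_value))
  invisible(x)
}
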