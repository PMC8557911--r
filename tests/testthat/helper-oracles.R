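# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written as plainly as possible, avoiding the code paths of the
# implementation it checks.

# -- fixtures -----------------------------------------------------------------

rand_dna_vec <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# toy table from the worked partition example: one sample, 100 reads split
# 70 freshwater / 25 sewer / 5 human fecal
toy_partition_fixture <- function() {
  seqs <- c(fw1 = strrep("A", 60), sw1 = strrep("C", 60), st1 = strrep("G", 60))
  counts <- matrix(c(70, 25, 5), nrow = 1,
                   dimnames = list("samp1", names(seqs)))
  table <- asv_table(counts, seqs)
  fw <- source_db("FW1", seqs[["fw1"]], "freshwater")
  sw <- source_db("SW1", seqs[["sw1"]], "sewer", 0.9)
  st <- source_db("ST1", seqs[["st1"]], "human_stool", 0.9)
  list(table = table, fw = fw, sw = sw, st = st)
}

# random partition instance: ASV sequences drawn from a shared pool so that
# database hits, cross-database hits, and misses all occur
rand_partition_instance <- function(n_asvs, n_samples, len = 30) {
  pool <- unique(rand_dna_vec(n_asvs * 2, len))
  fw_seq <- sample(pool, min(8, length(pool)))
  rest <- setdiff(pool, fw_seq)
  sw_seq <- c(sample(fw_seq, 2), sample(rest, min(6, length(rest))))
  rest2 <- setdiff(rest, sw_seq)
  st_seq <- c(sample(sw_seq, 1), sample(rest2, min(4, length(rest2))))
  fw <- source_db(paste0("FW", seq_along(fw_seq)), fw_seq, "freshwater")
  sw <- source_db(paste0("SW", seq_along(sw_seq)), sw_seq, "sewer",
                  stats::runif(length(sw_seq), 1e-4, 0.2))
  st <- source_db(paste0("ST", seq_along(st_seq)), st_seq, "human_stool",
                  stats::runif(length(st_seq), 1e-4, 0.2))
  asv_seq <- sample(pool, n_asvs)
  names(asv_seq) <- sprintf("ASV%03d", seq_len(n_asvs))
  counts <- matrix(stats::rpois(n_samples * n_asvs, 4) *
                     stats::rbinom(n_samples * n_asvs, 1, 0.6),
                   nrow = n_samples,
                   dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                   names(asv_seq)))
  if (any(rowSums(counts) == 0)) counts[rowSums(counts) == 0, 1] <- 1
  list(table = asv_table(counts, asv_seq), fw = fw, sw = sw, st = st)
}

# exact mean of f = c_river_hb / C_sewage,HB under the log-normal spec;
# bounds the bias of the analytic oracle, which treats ln(1 - f) as 0
mean_f_exact <- function(cfg) {
  cfg$c_river_hb / cfg$c_sewage_hb$geometric_mean *
    exp(cfg$c_sewage_hb$sigma^2 / 2)
}

# 99th percentile of f (small-f validity check for the analytic oracle)
f_q99 <- function(cfg) {
  cfg$c_river_hb / stats::qlnorm(0.01, cfg$c_sewage_hb$mu, cfg$c_sewage_hb$sigma)
}

# -- quantile / partition oracles --------------------------------------------

# type-7 quantile written from the order-statistic definition
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exhaustive reimplementation of the source partition: per-ASV loops,
# explicit string comparisons, manual percentile
oracle_partition <- function(table, fw, sw, st, apply_filter = TRUE, q = 5) {
  ids <- colnames(table$counts)
  totals <- rowSums(table$counts)
  keep <- totals > 0
  out <- data.frame(asv_id = ids, category = NA_character_,
                    reference_id = NA_character_, river_p5 = NA_real_,
                    stringsAsFactors = FALSE)
  find_in <- function(s, db) {
    for (k in seq_len(nrow(db))) if (db$sequence[k] == s) return(k)
    NA_integer_
  }
  for (i in seq_along(ids)) {
    s <- table$sequences[[ids[i]]]
    if (!is.na(find_in(s, fw))) {
      out$category[i] <- "freshwater"
      out$reference_id[i] <- fw$reference_id[find_in(s, fw)]
      next
    }
    ra <- table$counts[keep, ids[i]] / totals[keep]
    p5 <- oracle_quantile(ra, q / 100)
    k_st <- find_in(s, st)
    k_sw <- find_in(s, sw)
    if (!is.na(k_st)) {
      out$river_p5[i] <- p5
      if (!apply_filter || p5 < st$sewage_p95[k_st]) {
        out$category[i] <- "human_fecal"
        out$reference_id[i] <- st$reference_id[k_st]
      } else {
        out$category[i] <- "uncategorized"
      }
    } else if (!is.na(k_sw)) {
      out$river_p5[i] <- p5
      if (!apply_filter || p5 < sw$sewage_p95[k_sw]) {
        out$category[i] <- "sewer"
        out$reference_id[i] <- sw$reference_id[k_sw]
      } else {
        out$category[i] <- "uncategorized"
      }
    } else {
      out$category[i] <- "uncategorized"
    }
  }
  out
}

# -- indicator oracle ---------------------------------------------------------

# brute-force enumeration over all (ASV, group) pairs using explicit loops
oracle_indicators <- function(table, grouping, min_spec = 0.8, min_sens = 0.8) {
  ids <- colnames(table$counts)
  samples <- intersect(rownames(table$counts), names(grouping))
  g <- as.character(grouping[samples])
  groups <- sort(unique(g))
  totals <- rowSums(table$counts[samples, , drop = FALSE])
  res <- list()
  for (a in ids) {
    best <- NULL
    for (k in groups) {
      in_g <- samples[g == k]
      means <- vapply(groups, function(kk) {
        ss <- samples[g == kk]
        mean(table$counts[ss, a] / totals[ss])
      }, numeric(1))
      A <- if (sum(means) > 0) means[[k]] / sum(means) else 0
      B <- mean(table$counts[in_g, a] > 0)
      if (is.null(best) || A * B > best$score + 1e-15) {
        best <- list(group = k, A = A, B = B, score = A * B)
      }
    }
    res[[a]] <- data.frame(asv_id = a, group = best$group,
                           specificity = best$A, sensitivity = best$B,
                           strong = best$A >= min_spec && best$B >= min_sens,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

# -- PERMANOVA oracle ---------------------------------------------------------

# pseudo-F via the Gower-centred inner-product matrix and hat-matrix traces
# (McArdle-Anderson formulation) -- an algebraically different route than the
# implementation's within-group sums
oracle_pseudo_f <- function(d, labels) {
  n <- nrow(d)
  g <- factor(labels)
  a <- nlevels(g)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- stats::model.matrix(~ g)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  tr <- function(m) sum(diag(m))
  ss_among <- tr(H %*% G %*% H)
  ss_resid <- tr((diag(n) - H) %*% G %*% (diag(n) - H))
  (ss_among / (a - 1)) / (ss_resid / (n - a))
}
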