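#' Configuration for the synthetic pollution study generator
#'
#' Defines a simulated river monitoring campaign with known ground truth:
#' a grid of sites and sampling dates, three source reference databases
#' (freshwater, sewer, human stool) plus an unlabelled terrestrial pool,
#' per-sample sewage volumetric fractions `f`, and an HB qPCR marker coupled
#' to `f`. Defaults emulate a mixed urban/rural basin campaign: 16 sites
#' sampled on 5 dates, with `f` log-normal around 3e-4 (GSD 3) so that
#' sewage-sequence proportions span roughly 0.3% to 30%.
#'
#' @param n_sites Number of sampling sites (default 16).
#' @param n_dates Number of sampling dates per site (default 5).
#' @param urban_fraction Fraction of sites classed urban, in `[0, 1]`.
#' @param n_freshwater_refs,n_sewer_refs,n_stool_refs Sizes of the three
#'   reference databases.
#' @param n_terrestrial_asvs Number of unlabelled background ASVs matching no
#'   database (these exercise the "uncategorized" fallback).
#' @param amplicon_length Length (bp) of simulated amplicons; `>= 50`.
#' @param sewage_fraction_spec [lognormal_spec()] for per-sample `f`,
#'   truncated at `f_truncation`; `NULL` sets `f = 0` for every sample (an
#'   unpolluted control study).
#' @param depth_per_sample Reads per sample, `>= 100`.
#' @param hb_noise_gsd Geometric SD of multiplicative measurement noise on
#'   the HB observation; 1 disables noise.
#' @param c_sewage_hb_spec [lognormal_spec()] for the per-sample sewage HB
#'   concentration (CN/100 ml).
#' @param c_sewage_cells_spec,c_river_cells_spec [lognormal_spec()]s for
#'   per-sample total cell concentrations (cells/100 ml).
#' @param loq_cn_100ml Limit of quantification (CN/100 ml).
#' @param lod_cn_100ml Limit of detection; default half the LOQ.
#' @param dirichlet_overdispersion Optional positive scalar; when set,
#'   per-sample compositions are resampled from a Dirichlet with this
#'   concentration times the mixture proportions (compositional
#'   overdispersion). `NULL` (default) keeps pure multinomial sampling.
#' @param f_truncation Upper truncation bound for `f` (redrawn above it);
#'   `NULL` disables truncation, which errors if the spec has mass at
#'   `f >= 1`.
#' @param sewage_p95_range Two-element range of the log-uniform draw for the
#'   simulated 95th-percentile sewage relative abundances attached to sewer
#'   and stool references.
#' @param seed Integer seed; the whole bundle is a pure function of
#'   (config, seed).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 16L,
                             n_dates = 5L,
                             urban_fraction = 0.5,
                             n_freshwater_refs = 150L,
                             n_sewer_refs = 60L,
                             n_stool_refs = 20L,
                             n_terrestrial_asvs = 80L,
                             amplicon_length = 370L,
                             sewage_fraction_spec = lognormal_spec(3e-4, 3),
                             depth_per_sample = 50000L,
                             hb_noise_gsd = 1.2,
                             c_sewage_hb_spec = lognormal_spec(7.8e6, 3),
                             c_sewage_cells_spec = lognormal_spec(1.8e10, 2),
                             c_river_cells_spec = lognormal_spec(1e8, 2),
                             loq_cn_100ml = 180,
                             lod_cn_100ml = NULL,
                             dirichlet_overdispersion = NULL,
                             f_truncation = 0.99,
                             sewage_p95_range = c(1e-4, 1e-1),
                             seed = 1L) {
  counts <- c(n_sites = n_sites, n_dates = n_dates)
  for (nm in names(counts)) {
    if (!is_scalar_number(counts[[nm]]) || counts[[nm]] < 1) {
      stop(sprintf("'%s' must be >= 1", nm), call. = FALSE)
    }
  }
  for (nm in c("n_freshwater_refs", "n_sewer_refs", "n_stool_refs",
               "n_terrestrial_asvs")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  if (!is_scalar_number(urban_fraction) || urban_fraction < 0 || urban_fraction > 1) {
    stop("'urban_fraction' must lie in [0, 1]", call. = FALSE)
  }
  if (!is_scalar_number(amplicon_length) || amplicon_length < 50) {
    stop("'amplicon_length' must be >= 50 (shorter amplicons make exact matching meaningless)",
         call. = FALSE)
  }
  if (!is_scalar_number(depth_per_sample) || depth_per_sample < 100) {
    stop("'depth_per_sample' must be >= 100", call. = FALSE)
  }
  stopifnot(is.null(sewage_fraction_spec) || is_lognormal_spec(sewage_fraction_spec),
            is_lognormal_spec(c_sewage_hb_spec),
            is_lognormal_spec(c_sewage_cells_spec),
            is_lognormal_spec(c_river_cells_spec))
  if (!is_scalar_number(hb_noise_gsd) || hb_noise_gsd < 1) {
    stop("'hb_noise_gsd' must be >= 1", call. = FALSE)
  }
  if (is.null(lod_cn_100ml)) lod_cn_100ml <- loq_cn_100ml / 2
  if (lod_cn_100ml > loq_cn_100ml) {
    stop("LOD cannot exceed LOQ", call. = FALSE)
  }
  if (!is.null(f_truncation) &&
      (!is_scalar_number(f_truncation) || f_truncation <= 0 || f_truncation >= 1)) {
    stop("'f_truncation' must lie in (0, 1) or be NULL", call. = FALSE)
  }
  if (is.null(f_truncation) && !is.null(sewage_fraction_spec) &&
      quantile_lognormal(sewage_fraction_spec, 1 - 1e-12) >= 1) {
    stop("sewage_fraction_spec can produce f >= 1; enable truncation", call. = FALSE)
  }
  if (length(sewage_p95_range) != 2L || any(sewage_p95_range <= 0) ||
      any(sewage_p95_range > 1) || sewage_p95_range[1] > sewage_p95_range[2]) {
    stop("'sewage_p95_range' must be an increasing pair in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_sites = as.integer(n_sites), n_dates = as.integer(n_dates),
         urban_fraction = urban_fraction,
         n_freshwater_refs = as.integer(n_freshwater_refs),
         n_sewer_refs = as.integer(n_sewer_refs),
         n_stool_refs = as.integer(n_stool_refs),
         n_terrestrial_asvs = as.integer(n_terrestrial_asvs),
         amplicon_length = as.integer(amplicon_length),
         sewage_fraction_spec = sewage_fraction_spec,
         depth_per_sample = as.integer(depth_per_sample),
         hb_noise_gsd = hb_noise_gsd,
         c_sewage_hb_spec = c_sewage_hb_spec,
         c_sewage_cells_spec = c_sewage_cells_spec,
         c_river_cells_spec = c_river_cells_spec,
         loq_cn_100ml = loq_cn_100ml,
         lod_cn_100ml = lod_cn_100ml,
         dirichlet_overdispersion = dirichlet_overdispersion,
         f_truncation = f_truncation,
         sewage_p95_range = sewage_p95_range,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# n unique random DNA strings of length len, all distinct from `avoid`
random_dna <- function(n, len, avoid = character()) {
  if (n == 0L) return(character())
  seqs <- character(0)
  pool <- c(avoid)
  while (length(seqs) < n) {
    need <- n - length(seqs)
    cand <- vapply(seq_len(need), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    cand <- setdiff(unique(cand), pool)
    seqs <- c(seqs, cand)
    pool <- c(pool, cand)
  }
  seqs[seq_len(n)]
}

#' Generate the three source reference databases
#'
#' Reference sequences are random DNA strings of `amplicon_length` over
#' {A,C,G,T}; the freshwater, sewer, and human-stool databases are pairwise
#' disjoint at the full-sequence level. Sewer and stool references carry a
#' simulated 95th-percentile relative abundance in raw sewage, drawn
#' log-uniformly over `config$sewage_p95_range` (the range is recorded as an
#' attribute of each sewage-side database).
#'
#' @param config A [synthetic_config()].
#' @return Named list of three [source_db()]s: `freshwater`, `sewer`,
#'   `human_stool`.
#' @export
generate_reference_databases <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(derive_seed(config$seed, 1), {
    n_fw <- config$n_freshwater_refs
    n_sw <- config$n_sewer_refs
    n_st <- config$n_stool_refs
    all_seqs <- random_dna(n_fw + n_sw + n_st, config$amplicon_length)
    fw_seqs <- all_seqs[seq_len(n_fw)]
    sw_seqs <- all_seqs[n_fw + seq_len(n_sw)]
    st_seqs <- all_seqs[n_fw + n_sw + seq_len(n_st)]
    draw_p95 <- function(n) {
      rng <- log(config$sewage_p95_range)
      exp(stats::runif(n, rng[1], rng[2]))
    }
    fw <- source_db(sprintf("FW%04d", seq_len(n_fw)), fw_seqs, "freshwater")
    sw <- source_db(sprintf("SW%04d", seq_len(n_sw)), sw_seqs, "sewer",
                    draw_p95(n_sw))
    st <- source_db(sprintf("ST%04d", seq_len(n_st)), st_seqs, "human_stool",
                    draw_p95(n_st))
    attr(sw, "sewage_p95_range") <- config$sewage_p95_range
    attr(st, "sewage_p95_range") <- config$sewage_p95_range
    list(freshwater = fw, sewer = sw, human_stool = st)
  })
}

# draw f from the config spec with upper truncation by redraw
draw_sewage_fractions <- function(config, n) {
  spec <- config$sewage_fraction_spec
  if (is.null(spec)) return(rep(0, n))
  f <- draw_lognormal(spec, n)
  if (!is.null(config$f_truncation)) {
    bad <- f > config$f_truncation
    tries <- 0L
    while (any(bad)) {
      f[bad] <- draw_lognormal(spec, sum(bad))
      bad <- f > config$f_truncation
      tries <- tries + 1L
      if (tries > 1000L) stop("truncation rejection did not converge", call. = FALSE)
    }
  } else if (any(f >= 1)) {
    stop("drew f >= 1 with truncation disabled", call. = FALSE)
  }
  f
}

#' Generate river samples with known sewage fractions
#'
#' For each of the `n_sites * n_dates` samples, a true sewage read fraction
#' `r_true` is computed from the sample's drawn volumetric fraction `f` and
#' its drawn total cell concentrations via the composition form of
#' [sewage_read_fraction()]. The sample composition is then
#' `(1 - r_true)` times a fixed freshwater-plus-terrestrial background
#' profile plus `r_true` times a fixed sewage (sewer + stool) profile, and
#' reads are drawn multinomially at `depth_per_sample`.
#'
#' @param config A [synthetic_config()].
#' @param dbs Reference databases from [generate_reference_databases()].
#' @return List with elements `table` (an [asv_table()]), `metadata`
#'   (data frame: `sample_id`, `site`, `date`, `land_use`, `condition`,
#'   `stream_order`, `pct_developed`), and `truth` (list: per-sample `f`,
#'   `r_true`, cell concentration draws, and per-ASV `asv_source` including
#'   `"terrestrial"` for the unlabelled pool).
#' @export
generate_river_samples <- function(config, dbs) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_freshwater_refs + config$n_terrestrial_asvs == 0L) {
    stop("background community is empty: need freshwater references or terrestrial ASVs",
         call. = FALSE)
  }
  with_seed(derive_seed(config$seed, 2), {
    ref_seqs <- c(dbs$freshwater$sequence, dbs$sewer$sequence,
                  dbs$human_stool$sequence)
    terr_seqs <- random_dna(config$n_terrestrial_asvs, config$amplicon_length,
                            avoid = ref_seqs)
    asv_seq <- c(dbs$freshwater$sequence, terr_seqs,
                 dbs$sewer$sequence, dbs$human_stool$sequence)
    asv_id <- c(dbs$freshwater$reference_id,
                if (config$n_terrestrial_asvs)
                  sprintf("TR%04d", seq_len(config$n_terrestrial_asvs)),
                dbs$sewer$reference_id, dbs$human_stool$reference_id)
    asv_source <- c(rep("freshwater", config$n_freshwater_refs),
                    rep("terrestrial", config$n_terrestrial_asvs),
                    rep("sewer", config$n_sewer_refs),
                    rep("human_stool", config$n_stool_refs))
    names(asv_source) <- asv_id
    names(asv_seq) <- asv_id

    n_bg <- config$n_freshwater_refs + config$n_terrestrial_asvs
    n_sewage <- config$n_sewer_refs + config$n_stool_refs
    if (n_sewage == 0L && !is.null(config$sewage_fraction_spec)) {
      stop("sewage community is empty: need sewer or stool references", call. = FALSE)
    }
    # fixed community profiles (log-normal abundance structure)
    bg_w <- stats::rlnorm(n_bg, 0, 1.5); bg_w <- bg_w / sum(bg_w)
    sewage_w <- stats::rlnorm(n_sewage, 0, 1.5); sewage_w <- sewage_w / sum(sewage_w)

    n_samples <- config$n_sites * config$n_dates
    site <- rep(sprintf("S%02d", seq_len(config$n_sites)), each = config$n_dates)
    date <- rep(sprintf("D%d", seq_len(config$n_dates)), times = config$n_sites)
    sample_id <- paste(site, date, sep = "_")

    n_urban <- round(config$n_sites * config$urban_fraction)
    urban_sites <- sample(seq_len(config$n_sites), n_urban)
    land_use_site <- ifelse(seq_len(config$n_sites) %in% urban_sites,
                            "urban", "rural")
    pct_dev_site <- ifelse(land_use_site == "urban",
                           stats::runif(config$n_sites, 40, 95),
                           stats::runif(config$n_sites, 2, 35))
    stream_order_site <- sample(1:6, config$n_sites, replace = TRUE)

    f <- draw_sewage_fractions(config, n_samples)
    cs_cells <- draw_lognormal(config$c_sewage_cells_spec, n_samples)
    cr_cells <- draw_lognormal(config$c_river_cells_spec, n_samples)
    r_true <- sewage_read_fraction(f, cs_cells, cr_cells, "composition")

    counts <- matrix(0L, nrow = n_samples, ncol = length(asv_id),
                     dimnames = list(sample_id, asv_id))
    for (i in seq_len(n_samples)) {
      p <- c((1 - r_true[i]) * bg_w, r_true[i] * sewage_w)
      if (!is.null(config$dirichlet_overdispersion)) {
        alpha <- config$dirichlet_overdispersion * p
        g <- stats::rgamma(length(alpha), shape = alpha)
        if (sum(g) > 0) p <- g / sum(g)
      }
      counts[i, ] <- stats::rmultinom(1, config$depth_per_sample, p)[, 1]
    }

    names(f) <- names(r_true) <- sample_id
    metadata <- data.frame(
      sample_id = sample_id,
      site = site,
      date = date,
      land_use = rep(land_use_site, each = config$n_dates),
      condition = rep(ifelse(pct_dev_site > 50, "impacted", "good"),
                      each = config$n_dates),
      stream_order = rep(stream_order_site, each = config$n_dates),
      pct_developed = rep(round(pct_dev_site, 1), each = config$n_dates),
      stringsAsFactors = FALSE
    )
    list(
      table = asv_table(counts, asv_seq),
      metadata = metadata,
      truth = list(f = f, r_true = r_true, asv_source = asv_source,
                   c_sewage_cells = cs_cells, c_river_cells = cr_cells,
                   hb_true = NULL)
    )
  })
}

#' Generate HB qPCR observations coupled to the true sewage fractions
#'
#' The true HB concentration of a sample is `f` times a per-sample draw of
#' the sewage HB concentration, times multiplicative log-normal measurement
#' noise with geometric SD `hb_noise_gsd`. Observations below the limit of
#' detection are reported as non-detects; detected observations below the
#' limit of quantification are flagged `below_loq`. Both the uncensored truth
#' and the censored observation are emitted.
#'
#' @param truth Ground-truth list from [generate_river_samples()] (uses `f`).
#' @param config A [synthetic_config()].
#' @return Data frame: `sample_id`, `hb_true_cn_100ml` (uncensored),
#'   `hb_obs_cn_100ml` (`NA` for non-detects), `censor`
#'   (`nondetect`/`below_loq`/`quantified`), `category`
#'   (`undetectable`/`unquantifiable`/`quantifiable`/`risk`).
#' @export
generate_hb_measurements <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  f <- truth$f
  if (is.null(f) || !length(f)) stop("ground truth has no sewage fractions", call. = FALSE)
  with_seed(derive_seed(config$seed, 3), {
    n <- length(f)
    c_shb <- draw_lognormal(config$c_sewage_hb_spec, n)
    hb_true <- f * c_shb
    noise <- if (config$hb_noise_gsd > 1) {
      stats::rlnorm(n, 0, log(config$hb_noise_gsd))
    } else rep(1, n)
    hb_obs <- hb_true * noise
    censor <- ifelse(hb_obs < config$lod_cn_100ml, "nondetect",
                     ifelse(hb_obs < config$loq_cn_100ml, "below_loq",
                            "quantified"))
    category <- hb_category(hb_obs, censor,
                            loq_cn_100ml = config$loq_cn_100ml,
                            risk_cn_100ml = 7800)
    data.frame(
      sample_id = names(f),
      hb_true_cn_100ml = hb_true,
      hb_obs_cn_100ml = ifelse(censor == "nondetect", NA_real_, hb_obs),
      censor = censor,
      category = category,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a complete synthetic pollution study
#'
#' Convenience wrapper chaining [generate_reference_databases()],
#' [generate_river_samples()] and [generate_hb_measurements()]; the result is
#' a pure function of the configuration (including its seed).
#'
#' @param config A [synthetic_config()].
#' @return List with `databases`, `table`, `metadata`, `truth` (with
#'   `hb_true` filled in), and `hb` (the qPCR observation table).
#' @export
simulate_pollution_study <- function(config = synthetic_config()) {
  dbs <- generate_reference_databases(config)
  rs <- generate_river_samples(config, dbs)
  hb <- generate_hb_measurements(rs$truth, config)
  rs$truth$hb_true <- stats::setNames(hb$hb_true_cn_100ml, hb$sample_id)
  list(databases = dbs, table = rs$table, metadata = rs$metadata,
       truth = rs$truth, hb = hb)
}
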