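small_config <- function(...) {
  args <- utils::modifyList(
    list(n_sites = 4, n_dates = 2, n_freshwater_refs = 30, n_sewer_refs = 12,
         n_stool_refs = 6, n_terrestrial_asvs = 10, amplicon_length = 80,
         depth_per_sample = 2000, seed = 123),
    list(...), keep.null = TRUE
  )
  do.call(synthetic_config, args)
}

test_that("reference databases are disjoint, sized as configured, deterministic", {
  cfg <- synthetic_config(n_freshwater_refs = 100, n_sewer_refs = 50,
                          n_stool_refs = 10, amplicon_length = 60, seed = 3)
  dbs <- generate_reference_databases(cfg)
  expect_identical(nrow(dbs$freshwater), 100L)
  expect_identical(nrow(dbs$sewer), 50L)
  expect_identical(nrow(dbs$human_stool), 10L)
  # brute-force pairwise comparison of all emitted sequences
  all_seqs <- c(dbs$freshwater$sequence, dbs$sewer$sequence,
                dbs$human_stool$sequence)
  expect_identical(length(all_seqs), 160L)
  expect_identical(anyDuplicated(all_seqs), 0L)
  for (s in dbs$freshwater$sequence) {
    expect_false(s %in% dbs$sewer$sequence)
    expect_false(s %in% dbs$human_stool$sequence)
  }
  dbs2 <- generate_reference_databases(cfg)
  expect_identical(dbs, dbs2)
})

test_that("empty sewer database is generated when requested", {
  cfg <- small_config(n_sewer_refs = 0)
  dbs <- generate_reference_databases(cfg)
  expect_identical(nrow(dbs$sewer), 0L)
  expect_gt(nrow(dbs$freshwater), 0L)
  expect_gt(nrow(dbs$human_stool), 0L)
})

test_that("sewage-side references carry p95 values from the recorded range", {
  cfg <- small_config()
  dbs <- generate_reference_databases(cfg)
  rng <- attr(dbs$sewer, "sewage_p95_range")
  expect_identical(rng, cfg$sewage_p95_range)
  expect_true(all(dbs$sewer$sewage_p95 >= rng[1] & dbs$sewer$sewage_p95 <= rng[2]))
  expect_true(all(dbs$human_stool$sewage_p95 >= rng[1] &
                  dbs$human_stool$sewage_p95 <= rng[2]))
  expect_true(all(is.na(dbs$freshwater$sewage_p95)))
})

test_that("configuration validation rejects degenerate settings", {
  expect_error(synthetic_config(amplicon_length = 40), "amplicon_length")
  expect_error(synthetic_config(depth_per_sample = 50), "depth_per_sample")
  expect_error(synthetic_config(urban_fraction = 1.2), "urban_fraction")
  expect_error(synthetic_config(n_sites = 0), "n_sites")
  # an untruncated f distribution with mass at f >= 1 is rejected up front
  expect_error(
    synthetic_config(sewage_fraction_spec = lognormal_spec(0.5, 4),
                     f_truncation = NULL),
    "f >= 1"
  )
})

test_that("whole bundle is a pure function of config and seed", {
  cfg <- small_config()
  b1 <- simulate_pollution_study(cfg)
  b2 <- simulate_pollution_study(cfg)
  expect_identical(b1$table$counts, b2$table$counts)
  expect_identical(b1$truth$f, b2$truth$f)
  expect_identical(b1$hb, b2$hb)
  b3 <- simulate_pollution_study(small_config(seed = 999))
  expect_false(identical(b1$table$counts, b3$table$counts))
})

test_that("read counts sum to the configured depth in every sample", {
  b <- simulate_pollution_study(small_config())
  expect_true(all(rowSums(b$table$counts) == 2000))
})

test_that("unpolluted study (f = 0) puts no reads on sewage-derived ASVs", {
  cfg <- small_config(sewage_fraction_spec = NULL)
  b <- simulate_pollution_study(cfg)
  expect_true(all(b$truth$f == 0))
  sewage_asvs <- names(b$truth$asv_source)[
    b$truth$asv_source %in% c("sewer", "human_stool")]
  expect_true(all(b$table$counts[, sewage_asvs] == 0))
  expect_true(all(b$hb$censor == "nondetect"))
  expect_true(all(b$hb$category == "undetectable"))
})

test_that("empirical sewage read fraction matches the closed-form r(f)", {
  # f fixed at 0.001 and a fixed cell ratio of 100 gives
  # r = 0.1 / (0.1 + 0.999) ~= 0.0910; the multinomial estimate must sit
  # within 3 binomial standard errors at the configured depth
  cfg <- synthetic_config(
    n_sites = 6, n_dates = 2, n_freshwater_refs = 30, n_sewer_refs = 12,
    n_stool_refs = 6, n_terrestrial_asvs = 10, amplicon_length = 80,
    depth_per_sample = 20000,
    sewage_fraction_spec = lognormal_spec(0.001, 1),
    c_sewage_cells_spec = lognormal_spec(1e10, 1),
    c_river_cells_spec = lognormal_spec(1e8, 1),
    seed = 21
  )
  b <- simulate_pollution_study(cfg)
  r_expected <- (100 * 0.001) / (100 * 0.001 + 0.999)
  expect_equal(unname(b$truth$r_true), rep(r_expected, 12), tolerance = 1e-12)
  sewage_asvs <- names(b$truth$asv_source)[
    b$truth$asv_source %in% c("sewer", "human_stool")]
  est <- rowSums(b$table$counts[, sewage_asvs]) / rowSums(b$table$counts)
  se <- sqrt(r_expected * (1 - r_expected) / 20000)
  expect_true(all(abs(est - r_expected) < 3 * se))
})

test_that("noise-free HB measurements follow f times the sewage concentration", {
  cfg <- small_config(
    sewage_fraction_spec = lognormal_spec(0.001, 1),
    c_sewage_hb_spec = lognormal_spec(7.8e6, 1),
    hb_noise_gsd = 1
  )
  b <- simulate_pollution_study(cfg)
  expect_equal(unname(b$hb$hb_true_cn_100ml), rep(7800, 8), tolerance = 1e-12)
  expect_true(all(b$hb$censor == "quantified"))
  expect_true(all(b$hb$category == "risk"))  # 7800 is the inclusive boundary
})

test_that("detected observations below the LOQ are flagged below_loq", {
  cfg <- small_config(
    sewage_fraction_spec = lognormal_spec(2e-5, 1),  # HB = 156 CN/100 ml
    c_sewage_hb_spec = lognormal_spec(7.8e6, 1),
    hb_noise_gsd = 1
  )
  b <- simulate_pollution_study(cfg)
  expect_equal(unname(b$hb$hb_true_cn_100ml), rep(156, 8), tolerance = 1e-9)
  expect_true(all(b$hb$censor == "below_loq"))
  expect_true(all(b$hb$category == "unquantifiable"))
  expect_true(all(b$hb$hb_obs_cn_100ml < 180 & b$hb$hb_obs_cn_100ml >= 90))
})

test_that("true HB concentration is nondecreasing in f at fixed sewage HB", {
  cfg <- small_config(c_sewage_hb_spec = lognormal_spec(7.8e6, 1),
                      hb_noise_gsd = 1)
  b <- simulate_pollution_study(cfg)
  ord <- order(b$truth$f)
  expect_true(all(diff(b$hb$hb_true_cn_100ml[ord]) >= 0))
})

test_that("Dirichlet overdispersion keeps depth but perturbs compositions", {
  cfg1 <- small_config()
  cfg2 <- small_config(dirichlet_overdispersion = 50)
  b1 <- simulate_pollution_study(cfg1)
  b2 <- simulate_pollution_study(cfg2)
  expect_true(all(rowSums(b2$table$counts) == 2000))
  expect_false(identical(b1$table$counts, b2$table$counts))
})
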