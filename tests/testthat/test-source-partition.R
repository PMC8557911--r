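test_that("exact matching is identity on references and rejects near-misses", {
  db <- source_db(c("R1", "R2"), c("ACGTACGTAC", "TTTTGGGGCC"), "freshwater")
  expect_identical(exact_match("ACGTACGTAC", db), "R1")
  expect_identical(exact_match("acgtacgtac", db), "R1")  # case-insensitive
  expect_identical(exact_match("ACGTACGTAA", db), NA_character_)  # 1 substitution
  expect_identical(exact_match("ACGTACGT", db), NA_character_)    # truncated
  expect_error(exact_match("ACGN", db), "ambiguity")
})

test_that("exact matching agrees with brute-force all-pairs comparison", {
  set.seed(42)
  refs <- unique(rand_dna_vec(400, 40))
  db <- source_db(paste0("R", seq_along(refs)), refs, "freshwater")
  # queries: half planted reference sequences, half random
  queries <- c(sample(refs, 200), rand_dna_vec(200, 40))
  got <- exact_match(queries, db)
  oracle <- vapply(queries, function(s) {
    hit <- NA_character_
    for (k in seq_along(refs)) if (refs[k] == s) { hit <- db$reference_id[k]; break }
    hit
  }, character(1), USE.NAMES = FALSE)
  expect_identical(got, oracle)
})

test_that("river percentile uses inclusive linear interpolation with zeros", {
  abund <- c(0, 0, 0.002, 0.004, 0.01)
  counts <- matrix(0, nrow = 5, ncol = 2,
                   dimnames = list(paste0("s", 1:5), c("A1", "A2")))
  counts[, "A1"] <- round(abund * 1000)
  counts[, "A2"] <- 1000 - counts[, "A1"]
  tab <- asv_table(counts, c(A1 = "ACGT", A2 = "TTTT"))
  expect_equal(river_percentile("A1", tab, q = 5), oracle_quantile(abund, 0.05))
  expect_equal(river_percentile("A1", tab, q = 5), 0)           # h = 1.2 between two zeros
  expect_equal(river_percentile("A1", tab, q = 30), 0.0004)     # hand: 0 + 0.2*(0.002-0)
  expect_equal(river_percentile("A1", tab, q = 50), 0.002)
  # constant relative abundance is its own percentile
  cc <- matrix(c(1, 99, 2, 198, 3, 297), nrow = 3, byrow = TRUE,
               dimnames = list(paste0("s", 1:3), c("A1", "A2")))
  tab2 <- asv_table(cc, c(A1 = "ACGT", A2 = "TTTT"))
  expect_equal(river_percentile("A1", tab2, q = 5), 0.01)
  # an ASV absent everywhere has percentile 0
  cc2 <- matrix(c(0, 10, 0, 20), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("A1", "A2")))
  tab3 <- asv_table(cc2, c(A1 = "ACGT", A2 = "TTTT"))
  expect_equal(river_percentile("A1", tab3, q = 5), 0)
  expect_error(river_percentile("nope", tab3), "unknown ASV")
})

test_that("inclusion filter is strict", {
  expect_true(sewage_inclusion_filter(0.0001, 0.01))
  expect_false(sewage_inclusion_filter(0.01, 0.01))  # equality excludes
  expect_false(sewage_inclusion_filter(0.05, 0.01))
  expect_error(sewage_inclusion_filter(0.1, NA_real_), "required")
})

test_that("partition applies freshwater precedence and the filter", {
  seqs <- c(both = strrep("A", 40), st = strrep("C", 40),
            sw = strrep("G", 40), none = strrep("T", 40),
            rare = paste(rep("AC", 20), collapse = ""))
  counts <- matrix(c(10, 10, 10, 10, 1,
                     10, 10, 10, 10, 0),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), names(seqs)))
  tab <- asv_table(counts, seqs)
  fw <- source_db("FW1", seqs[["both"]], "freshwater")
  sw <- source_db(c("SW1", "SW2"), c(seqs[["both"]], seqs[["sw"]]), "sewer",
                  c(0.9, 0.9))
  st <- source_db(c("ST1", "ST2"), c(seqs[["st"]], seqs[["rare"]]),
                  "human_stool", c(0.9, 1e-6))
  part <- partition_sources(tab, fw, sw, st)
  cats <- setNames(part$category, part$asv_id)
  expect_identical(cats[["both"]], "freshwater")   # matches fw and sewer
  expect_identical(cats[["st"]], "human_fecal")    # passes filter
  expect_identical(cats[["sw"]], "sewer")
  expect_identical(cats[["none"]], "uncategorized")
  # 'rare' matches stool but its river p5 (~0.012) exceeds p95 = 1e-6
  expect_identical(cats[["rare"]], "uncategorized")
  expect_false(is.na(part$river_p5[part$asv_id == "rare"]))
  # permissive mode admits it
  part2 <- partition_sources(tab, fw, sw, st, apply_filter = FALSE)
  expect_identical(part2$category[part2$asv_id == "rare"], "human_fecal")
})

test_that("freshwater membership can be supplied as flags", {
  seqs <- c(a = strrep("A", 40), b = strrep("C", 40))
  counts <- matrix(c(5, 5), nrow = 1, dimnames = list("s1", names(seqs)))
  tab <- asv_table(counts, seqs)
  empty_fw <- source_db(character(), character(), character())
  sw <- source_db("SW1", seqs[["a"]], "sewer", 0.9)
  st <- source_db(character(), character(), character())
  part <- partition_sources(tab, empty_fw, sw, st,
                            freshwater_flags = c(a = TRUE, b = FALSE))
  expect_identical(part$category[part$asv_id == "a"], "freshwater")
  expect_identical(part$category[part$asv_id == "b"], "uncategorized")
})

test_that("duplicate ASV sequences are rejected", {
  seqs <- c(a = "ACGT", b = "ACGT")
  counts <- matrix(c(1, 2), nrow = 1, dimnames = list("s1", c("a", "b")))
  tab <- asv_table(counts, seqs)
  fw <- source_db(character(), character(), character())
  expect_error(partition_sources(tab, fw, fw, fw), "dereplicate")
})

test_that("category abundances are the summed member relative abundances", {
  fx <- toy_partition_fixture()
  part <- partition_sources(fx$table, fx$fw, fx$sw, fx$st)
  cra <- category_relative_abundance(fx$table, part)
  expect_equal(unname(cra["samp1", ]), c(0.70, 0.05, 0.25, 0))
  expect_equal(sum(cra["samp1", ]), 1, tolerance = 1e-9)
  expect_equal(unname(sewage_proportion(fx$table, part)["samp1"]), 0.30)
  expect_equal(unname(sewage_proportion(fx$table, part,
                                        include_human_fecal = FALSE)["samp1"]),
               0.25)
})

test_that("all-freshwater and all-sewer samples hit the extremes", {
  seqs <- c(fw1 = strrep("A", 40), sw1 = strrep("C", 40))
  counts <- matrix(c(50, 0,
                     0, 80,
                     0, 0),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("all_fw", "all_sw", "empty"), names(seqs)))
  tab <- asv_table(counts, seqs)
  fw <- source_db("FW1", seqs[["fw1"]], "freshwater")
  sw <- source_db("SW1", seqs[["sw1"]], "sewer", 0.9)
  st <- source_db(character(), character(), character())
  part <- partition_sources(tab, fw, sw, st)
  cra <- category_relative_abundance(tab, part)
  expect_equal(unname(cra["all_fw", ]), c(1, 0, 0, 0))
  sp <- sewage_proportion(tab, part)
  expect_equal(unname(sp["all_fw"]), 0)
  expect_equal(unname(sp["all_sw"]), 1)
  expect_true(is.na(sp[["empty"]]))  # zero-total sample reported missing
})

test_that("partition is complete and disjoint on random instances", {
  set.seed(77)
  for (i in 1:20) {
    inst <- rand_partition_instance(sample(10:40, 1), sample(3:8, 1))
    part <- partition_sources(inst$table, inst$fw, inst$sw, inst$st)
    expect_setequal(part$asv_id, colnames(inst$table$counts))
    expect_identical(anyDuplicated(part$asv_id), 0L)
    expect_true(all(part$category %in%
                    c("freshwater", "human_fecal", "sewer", "uncategorized")))
    # freshwater assignments never carry a sewage-side reference
    fw_rows <- part$category == "freshwater"
    expect_true(all(part$reference_id[fw_rows] %in%
                    c(inst$fw$reference_id, "flagged")))
  }
})

test_that("raising abundance everywhere can only exclude, never include", {
  seqs <- c(a = strrep("A", 40), b = strrep("C", 40))
  fw <- source_db(character(), character(), character())
  sw <- source_db("SW1", seqs[["a"]], "sewer", 0.01)
  st <- source_db(character(), character(), character())
  status_at <- function(k) {
    counts <- matrix(c(k, 1000 - k,
                       k, 1000 - k,
                       k, 1000 - k), nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("s", 1:3), names(seqs)))
    tab <- asv_table(counts, seqs)
    part <- partition_sources(tab, fw, sw, st)
    part$category[part$asv_id == "a"] == "sewer"
  }
  included <- vapply(c(1, 5, 9, 10, 50, 500), status_at, logical(1))
  # p5 = k/1000 crosses p95 = 0.01 at k = 10 (strict: equality excludes)
  expect_identical(included, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(diff(as.integer(included)) <= 0))  # monotone exclusion
})

test_that("partition matches the brute-force oracle on random instances", {
  set.seed(2024)
  for (i in 1:100) {
    inst <- rand_partition_instance(sample(5:50, 1), sample(2:10, 1))
    filt <- i %% 2 == 0
    got <- partition_sources(inst$table, inst$fw, inst$sw, inst$st,
                             apply_filter = filt)
    want <- oracle_partition(inst$table, inst$fw, inst$sw, inst$st,
                             apply_filter = filt)
    expect_identical(got$category, want$category)
    expect_identical(got$reference_id, want$reference_id)
    expect_equal(got$river_p5, want$river_p5, tolerance = 1e-12)
  }
})

test_that("partition recovers ground truth on synthetic data", {
  cfg <- synthetic_config(n_sites = 4, n_dates = 2, n_freshwater_refs = 40,
                          n_sewer_refs = 15, n_stool_refs = 8,
                          n_terrestrial_asvs = 12, amplicon_length = 80,
                          depth_per_sample = 20000, seed = 5)
  b <- simulate_pollution_study(cfg)
  part <- partition_sources(b$table, b$databases$freshwater,
                            b$databases$sewer, b$databases$human_stool,
                            apply_filter = FALSE)
  truth <- b$truth$asv_source[part$asv_id]
  expected <- c(freshwater = "freshwater", sewer = "sewer",
                human_stool = "human_fecal", terrestrial = "uncategorized")
  seen <- colSums(b$table$counts)[part$asv_id] > 0
  expect_true(all(part$category[seen] == expected[truth[seen]]))
})
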