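test_that("sample ids parse into fixation/block/position", {
  out <- parse_sample_id(c("6_G_7", "24_H_11", "1_G_1"))
  expect_equal(out$fixation_hours, c(6L, 24L, 1L))
  expect_equal(out$block, c("G", "H", "G"))
  expect_equal(out$position, c(7L, 11L, 1L))
  expect_error(parse_sample_id("6G7"), "parse")
  expect_error(parse_sample_id("6_g_7"), "BLOCK")
})

test_that("cell count is four times the mean flank count", {
  expect_equal(estimate_cell_count(5000, 6000), 22000)
  expect_equal(estimate_cell_count(0, 0), 0)
  expect_equal(estimate_cell_count(2500, 2500), 10000)
  expect_error(estimate_cell_count(-1, 5), "non-negative")
})

test_that("position categories follow the surface rules on the worked profile", {
  counts <- c(4000, 12000, 13000, 12000, 25000, 26000,
              24000, 25000, 13000, 12000, 11000, 5000)
  lab <- categorize_positions(1:12, counts)
  expect_equal(unname(lab[c(1, 12)]), c("SURFACE_1", "SURFACE_1"))
  expect_equal(unname(lab[c(2, 3, 4, 9, 10, 11)]), rep("SURFACE_2", 6))
  expect_equal(unname(lab[5:8]), rep("INNER", 4))
})

test_that("equal counts give no SURFACE_1 and three SURFACE_2 per end", {
  lab <- categorize_positions(1:10, rep(20000, 10))
  expect_equal(sum(lab == "SURFACE_1"), 0)
  expect_equal(unname(lab), c(rep("SURFACE_2", 3), rep("INNER", 4),
                              rep("SURFACE_2", 3)))
})

test_that("position labels are symmetric under reversing the order", {
  set.seed(3)
  for (i in 1:10) {
    counts <- round(runif(12, 3000, 30000))
    fwd <- categorize_positions(1:12, counts)
    rev_ <- categorize_positions(1:12, rev(counts))
    expect_equal(unname(fwd), rev(unname(rev_)))
  }
  expect_error(categorize_positions(integer(0), numeric(0)), "no positions")
})

test_that("generator block profiles are recovered by the categorizer", {
  cfg <- tiny_config(seed = 9)
  set.seed(9)
  blk <- simulate_block(cfg, "G", 6)
  lab <- categorize_positions(blk$position, blk$cell_count)
  expect_equal(unname(lab), blk$true_category)

  # drop factor 1: no SURFACE_1 labels arise
  cfg2 <- tiny_config(seed = 9, surface1_factor = 1, surface2_factor = 1)
  set.seed(10)
  blk2 <- simulate_block(cfg2, "G", 6)
  lab2 <- categorize_positions(blk2$position, blk2$cell_count)
  expect_equal(sum(lab2 == "SURFACE_1"), 0)
})

test_that("tail statistic measures the homozygous cluster displacement", {
  expect_equal(vaf_tail_statistic(rep(1, 50)), 0)
  expect_warning(t5 <- vaf_tail_statistic(rep(1, 5)), "undefined")
  expect_true(is.na(t5))
  # hom cluster shifted to 0.90 by 10% contamination
  vafs <- c(rep(0.5, 100), rep(0.90, 100))
  expect_equal(vaf_tail_statistic(vafs), 0.10)
  set.seed(1)
  noisy <- c(rep(0.5, 100), pmin(1, 0.90 + rnorm(200, 0, 0.005)))
  expect_lt(abs(vaf_tail_statistic(noisy) - (0.10 + qnorm(0.95) * 0.005)), 0.005)
  # het cluster is ignored (below the 0.7 cutoff)
  expect_equal(vaf_tail_statistic(c(rep(0.4, 100), rep(1, 20))), 0)
})

test_that("germline overlap fraction counts database hits", {
  db <- c("a", "b", "c")
  expect_equal(germline_overlap_fraction(c("a", "b"), db), 1)
  expect_equal(germline_overlap_fraction(c("x", "y"), db), 0)
  expect_equal(germline_overlap_fraction(character(0), db), 0)
  expect_equal(germline_overlap_fraction(c("a", "x"), db), 0.5)
})

test_that("contamination flag is two-stage: wide tail AND germline overlap", {
  th <- qc_thresholds()
  cohort <- c(0.02, 0.025, 0.03, 0.02, 0.022)
  expect_false(flag_contamination(0, cohort, overlap = 1, th))
  expect_true(flag_contamination(0.12, cohort, overlap = 0.9, th))
  expect_false(flag_contamination(0.12, cohort, overlap = 0, th)) # pure noise tail
  expect_false(flag_contamination(0.05, cohort, overlap = 0.9, th)) # tail too narrow
  expect_false(flag_contamination(NA_real_, cohort, overlap = 0.9, th))
  expect_error(flag_contamination(0.1, c(0.1, 0.2), 1, th), "at least 4")
})

test_that("QC groups: exclusion dominates, then position, then thresholds", {
  th <- qc_thresholds(min_cell_count = 10000, min_dna_input_ng = 20,
                      min_library_yield = 50, min_median_dedup_depth = 850)
  good <- list(cell_count = 25000, dna_yield_ng = 100, library_yield = 120,
               median_dedup_depth = 2000)
  expect_equal(qc_classify(good, "INNER", th), "PASS_INNER")
  expect_equal(qc_classify(good, "SURFACE_1", th), "SURFACE")
  expect_equal(qc_classify(good, "SURFACE_2", th), "SURFACE")
  expect_equal(qc_classify(good, "INNER", th, contamination_flag = TRUE), "EXCLUDED")
  expect_equal(qc_classify(good, "INNER", th, experiment_failed = TRUE), "EXCLUDED")
  bad_depth <- modifyList(good, list(median_dedup_depth = 500))
  expect_equal(qc_classify(bad_depth, "INNER", th), "FAIL_INNER")
  # surface failing thresholds is still SURFACE, never excluded
  expect_equal(qc_classify(bad_depth, "SURFACE_1", th), "SURFACE")
  missing_field <- good[-4]
  expect_error(qc_classify(missing_field, "INNER", th), "median_dedup_depth")
  # fields are not needed when the sample is excluded anyway
  expect_equal(qc_classify(missing_field, "INNER", th, experiment_failed = TRUE),
               "EXCLUDED")
})

test_that("contamination detector: no false flags at 0, full detection at >= 0.10", {
  cfg <- tiny_config(seed = 6)
  truth <- simulate_truth(cfg)
  set.seed(606)
  second <- simulate_second_genome(truth, cfg)
  db <- simulate_germline_db(second, cfg)
  known <- truth$truth$key
  fractions <- c(rep(0, 14), 0.05, 0.05, 0.10, 0.10, 0.20, 0.20)
  samples <- lapply(seq_along(fractions), function(i) {
    simulate_sample(truth, cfg, paste0("s", i), "INNER",
                    contamination_fraction = fractions[i],
                    second_genome = if (fractions[i] > 0) second else NULL)
  })
  cleaned <- lapply(samples, sim_clean, truth = truth)
  tails <- vapply(cleaned, function(s) vaf_tail_statistic(s$vaf), numeric(1))
  flags <- vapply(seq_along(cleaned), function(i) {
    fp <- call_false_positives(cleaned[[i]], known, truth$panel_cfg,
                               truth$ctr, "whole_panel")
    ov <- germline_overlap_fraction(variant_key(fp$fp_calls), db)
    flag_contamination(tails[i], tails, ov)
  }, logical(1))
  expect_false(any(flags[fractions == 0]))
  expect_true(all(flags[fractions >= 0.10]))
  # tail statistic close to its closed-form expectation at 10%
  t10 <- mean(tails[fractions == 0.10])
  exp10 <- expected_tail_statistic(0.10, cfg$contaminant_mismatch_frac,
                                   cfg$vaf_noise_sd)
  expect_lt(abs(t10 - exp10) / exp10, 0.2)
})

test_that("metadata reading derives id fields and cell counts", {
  p <- withr::local_tempfile(fileext = ".tsv")
  md <- data.frame(sample_id = c("6_G_7", "1_H_2"),
                   flank_count_a = c(5000, 2500), flank_count_b = c(6000, 2500),
                   dna_yield_ng = c(100, 50), library_yield = c(120, 80),
                   median_dedup_depth = c(2000, 1500),
                   experiment_failed = c(FALSE, TRUE))
  write.table(md, p, sep = "\t", row.names = FALSE, quote = FALSE)
  out <- read_sample_metadata(p)
  expect_equal(out$fixation_hours, c(6L, 1L))
  expect_equal(out$cell_count, c(22000, 10000))
  cls <- classify_samples(cbind(out, position_category = c("INNER", "INNER")))
  expect_equal(cls$group, c("PASS_INNER", "EXCLUDED"))
})
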