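test_that("truth simulation is deterministic and respects configuration", {
  cfg <- tiny_config(seed = 12)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$truth, t2$truth)
  expect_identical(t1$reference, t2$reference)
  expect_equal(nrow(t1$truth), cfg$n_het + cfg$n_hom)
  expect_equal(sum(t1$truth$zygosity == "HOM"), cfg$n_hom)
  expect_equal(unique(t1$truth$genotype_vaf[t1$truth$zygosity == "HET"]), 0.5)
  # all truth positions inside the assessable region, none in low-complexity
  expect_true(all(region_contains(t1$effective, t1$truth$chrom, t1$truth$pos)))
  # CTR is a subset of the panel
  expect_equal(total_bases(region_subtract(t1$ctr, t1$panel)), 0)

  cfg0 <- tiny_config(seed = 12, n_hom = 0, n_het = 30)
  t0 <- simulate_truth(cfg0)
  expect_true(all(t0$truth$genotype_vaf == 0.5))
  expect_error(simulate_truth(tiny_config(n_het = 3e5, n_hom = 0)),
               "exceed")
})

test_that("a null sample is the truth set with VAF jitter only", {
  cfg <- tiny_config(seed = 5, deamination_rate_inner_per_mb = 0,
                     noise_rate_per_mb = 0)
  truth <- simulate_truth(cfg)
  set.seed(50)
  s <- simulate_sample(truth, cfg, "s1", "INNER")
  expect_setequal(variant_key(s), truth$truth$key)
  expect_true(all(s$origin == "truth"))
  m <- match(variant_key(s), truth$truth$key)
  expect_lt(max(abs(s$vaf - truth$truth$genotype_vaf[m])), 6 * cfg$vaf_noise_sd)
  # zero FP against the truth-derived known set
  rep_ <- call_false_positives(sim_clean(s, truth), truth$truth$key,
                               truth$panel_cfg, truth$ctr, "whole_panel")
  expect_equal(rep_$fp_count, 0)
})

test_that("every emitted variant is tagged and origins are disjoint from truth", {
  cfg <- tiny_config(seed = 19)
  truth <- simulate_truth(cfg)
  set.seed(190)
  second <- simulate_second_genome(truth, cfg)
  s <- simulate_sample(truth, cfg, "s1", "SURFACE_1",
                       contamination_fraction = 0.2, second_genome = second)
  expect_true(all(s$origin %in% c("truth", "artifact", "contaminant", "noise")))
  expect_false(any(duplicated(variant_key(s))))
  nt <- s[s$origin != "truth", ]
  expect_false(any(variant_key(nt) %in% truth$truth$key))
  # artifacts are pure deamination substitutions on C/G reference bases
  art <- s[s$origin == "artifact", ]
  expect_true(all((art$ref == "C" & art$alt == "T") |
                    (art$ref == "G" & art$alt == "A")))
  # noise calls are OTHER-type substitutions
  noi <- s[s$origin == "noise", ]
  expect_true(all(classify_damage_type(noi$ref, noi$alt) == "OTHER"))
  expect_error(simulate_sample(truth, cfg, "x", "INNER",
                               contamination_fraction = 0.1), "second genome")
})

test_that("surface artifact counts follow the configured Poisson mean", {
  cfg <- tiny_config(seed = 23, panel_size_bases = 1e6,
                     deamination_rate_inner_per_mb = 4, surface_multiplier = 5)
  truth <- simulate_truth(cfg)
  eff_mb <- total_bases(truth$effective) / 1e6
  lambda <- 4 * 5 * eff_mb
  set.seed(230)
  counts <- replicate(50, {
    s <- simulate_sample(truth, cfg, "s", "SURFACE_1")
    sum(s$origin == "artifact")
  })
  se <- sqrt(lambda / 50)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # inner samples use the un-multiplied rate
  counts_in <- replicate(50, {
    s <- simulate_sample(truth, cfg, "s", "INNER")
    sum(s$origin == "artifact")
  })
  li <- 4 * eff_mb
  expect_lt(abs(mean(counts_in) - li), 3 * sqrt(li / 50))
})

test_that("cohorts are reproducible from the seed and follow the design", {
  cfg <- sim_config(seed = 31, panel_size_bases = 5e4, n_het = 30, n_hom = 20,
                    n_panels = 2)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$panels$panelA$samples, c2$panels$panelA$samples)
  # 8 blocks x 3 sections per panel
  expect_equal(nrow(c1$metadata), 2 * 8 * 3)
  expect_equal(sort(unique(c1$metadata$fixation_hours)), c(1, 2, 6, 24))
  expect_equal(sort(unique(c1$metadata$block)), c("G", "H"))
  # ids follow the underscore coding
  parsed <- parse_sample_id(c1$metadata$sample_id)
  expect_equal(parsed$fixation_hours, c1$metadata$fixation_hours)
  # panels draw disjoint positions
  pa <- unique(c1$metadata$position[c1$metadata$panel == "panelA"])
  pb <- unique(c1$metadata$position[c1$metadata$panel == "panelB"])
  expect_length(intersect(pa, pb), 0)

  # different run seed, same truth seed: same truth, different artifacts
  cfg3 <- sim_config(seed = 99, truth_seed = 31, panel_size_bases = 5e4,
                     n_het = 30, n_hom = 20, n_panels = 1)
  cfg4 <- sim_config(seed = 31, panel_size_bases = 5e4, n_het = 30, n_hom = 20,
                     n_panels = 1)
  t3 <- simulate_truth(cfg3)
  t4 <- simulate_truth(cfg4)
  expect_identical(t3$truth, t4$truth)
})

test_that("written cohorts round-trip through the standard file formats", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 8, panel_size_bases = 5e4, n_het = 25, n_hom = 15,
                    n_panels = 1, contamination_fractions = c("6_G_6" = 0.2))
  coh <- simulate_cohort(cfg, dir = dir)
  pd <- file.path(dir, "panelA")
  expect_true(file.exists(file.path(pd, "reference.fa")))

  target <- parse_bed(file.path(pd, "target.bed"))
  expect_equal(total_bases(target), 5e4)
  ctr <- parse_bed(file.path(pd, "ctr.bed"))
  expect_equal(total_bases(ctr), total_bases(coh$panels$panelA$truth$ctr))

  sid <- coh$metadata$sample_id[1]
  back <- read_sample_vcf(file.path(pd, paste0(sid, ".vcf")))
  orig <- coh$panels$panelA$samples[[sid]]
  orig <- orig[order(orig$chrom, orig$pos, orig$ref, orig$alt), ]
  expect_equal(back[, c("chrom", "pos", "ref", "alt")],
               orig[, c("chrom", "pos", "ref", "alt")],
               ignore_attr = TRUE)
  expect_equal(back$vaf, orig$vaf, tolerance = 1e-5)

  # the emitted reference agrees with the emitted alleles
  acc <- ref_accessor_from_fasta(file.path(pd, "reference.fa"))
  renorm <- left_align_and_trim(back, acc)
  expect_equal(renorm[, c("pos", "ref", "alt")], back[, c("pos", "ref", "alt")])

  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(md), nrow(coh$metadata))
  expect_true(all(c("cell_count", "true_category", "expected_gc_to_at") %in% names(md)))
})

test_that("cohort-level damage ordering: surface exceeds inner per seed suite", {
  for (seed in c(101, 202, 303)) {
    cfg <- sim_config(seed = seed, panel_size_bases = 2e5, n_het = 40,
                      n_hom = 25, n_panels = 1)
    coh <- simulate_cohort(cfg)
    truth <- coh$panels$panelA$truth
    md <- coh$metadata
    gc_counts <- vapply(md$sample_id, function(sid) {
      s <- coh$panels$panelA$samples[[sid]]
      rep_ <- call_false_positives(sim_clean(s, truth), truth$truth$key,
                                   truth$panel_cfg, truth$ctr, "whole_panel")
      rep_$type_counts[["GC_TO_AT"]]
    }, numeric(1))
    surf <- md$true_category != "INNER"
    expect_gt(mean(gc_counts[surf]), mean(gc_counts[!surf]))
  }
})
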