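#' Simulation configuration
#'
#' Parameters of the synthetic study generator. The defaults emulate the
#' design the pipeline targets: a diploid cell line sequenced on targeted
#' oncopanels after FFPE processing at four formalin fixation times
#' (1, 2, 6, 24 h), two blocks per fixation time, sections indexed by depth
#' with depressed cellularity at the block surfaces, low-VAF hydrolytic
#' deamination artifacts whose rate is elevated in surface sections and —
#' by default — independent of fixation time in inner sections, sporadic
#' noise calls, and optional cross-individual contamination that shifts the
#' homozygous VAF cluster left of 1.0.
#'
#' @param seed RNG seed for everything except the truth set.
#' @param truth_seed separate seed for the truth set and reference genome,
#'   so artifact placements can be varied while the germline truth is held
#'   fixed; defaults to `seed`.
#' @param panel_size_bases targeted region size (default 1.7 Mb, a typical
#'   mid-size hybrid-capture oncopanel).
#' @param low_complexity_fraction fraction of the panel flagged
#'   low-complexity and excluded from analysis.
#' @param ctr_fraction fraction of the panel inside the consensus
#'   high-confidence targeted region.
#' @param n_het,n_hom numbers of heterozygous (VAF 0.5) and homozygous
#'   (VAF 1.0) germline truth variants.
#' @param vaf_noise_sd Gaussian measurement noise on observed VAFs.
#' @param default_vaf_threshold panel-recommended VAF cutoff.
#' @param deamination_rate_inner_per_mb expected G:C>A:T artifacts per Mb
#'   in inner sections.
#' @param surface_multiplier artifact-rate multiplier for surface sections
#'   (>= 1).
#' @param fixation_effect_per_hour planted fixation-time effect on the
#'   inner artifact rate (relative increase per hour); 0 by default — no
#'   fixation effect, matching the null the pipeline should not reject.
#' @param artifact_vaf_mean,artifact_vaf_sd Beta-distribution moments of
#'   artifact VAFs; the default (mean 0.02, sd 0.002) sits above a 1\%
#'   calling threshold, almost entirely below 2.5\%, and entirely below
#'   5\%.
#' @param noise_rate_per_mb sporadic (non-FFPE) noise calls per Mb.
#' @param noise_vaf_shape Beta shape parameters of noise-call VAFs.
#' @param fixation_times fixation times (hours) of the block design.
#' @param sections_per_block sections cut per block (>= 7).
#' @param surface1_sections,surface2_sections sections per block end in the
#'   first and second surface category.
#' @param surface1_factor,surface2_factor cell-count scaling at the block
#'   surface relative to the inner mean.
#' @param inner_cell_mean,inner_cell_cv inner-section cell-count mean and
#'   coefficient of variation.
#' @param depth_mean,depth_sd per-call total sequencing depth distribution.
#' @param contaminant_mismatch_frac fraction `h` of host homozygous sites
#'   the contaminating genome does not share; contamination at fraction `f`
#'   displaces those sites to VAF `1 - f`.
#' @param germline_db_prob probability a contaminant variant is present in
#'   the synthetic germline database.
#' @param n_panels number of simulated panels (laboratories).
#' @param samples_per_block sections drawn evenly per block for each panel.
#' @param contamination_fractions optional named numeric vector
#'   (`sample_id -> fraction in [0, 0.5)`) applied in [simulate_cohort].
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1, truth_seed = seed,
                       panel_size_bases = 1.7e6,
                       low_complexity_fraction = 0.02,
                       ctr_fraction = 0.6,
                       n_het = 350, n_hom = 150,
                       vaf_noise_sd = 0.015,
                       default_vaf_threshold = 0.01,
                       deamination_rate_inner_per_mb = 2,
                       surface_multiplier = 5,
                       fixation_effect_per_hour = 0,
                       artifact_vaf_mean = 0.02, artifact_vaf_sd = 0.002,
                       noise_rate_per_mb = 0.5,
                       noise_vaf_shape = c(2, 38),
                       fixation_times = c(1, 2, 6, 24),
                       sections_per_block = 12,
                       surface1_sections = 1, surface2_sections = 3,
                       surface1_factor = 0.2, surface2_factor = 0.5,
                       inner_cell_mean = 25000, inner_cell_cv = 0.1,
                       depth_mean = 2000, depth_sd = 150,
                       contaminant_mismatch_frac = 0.5,
                       germline_db_prob = 0.9,
                       n_panels = 4, samples_per_block = 3,
                       contamination_fractions = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$surface_multiplier >= 1,
            cfg$deamination_rate_inner_per_mb >= 0,
            cfg$noise_rate_per_mb >= 0,
            cfg$sections_per_block >= 7)
  if (!is.null(contamination_fractions)) {
    stopifnot(all(contamination_fractions >= 0),
              all(contamination_fractions < 0.5))
  }
  structure(cfg, class = "SimulationConfig")
}

beta_shapes <- function(mean, sd) {
  v <- sd^2
  if (v >= mean * (1 - mean)) stop("beta sd too large for mean")
  nu <- mean * (1 - mean) / v - 1
  c(a = mean * nu, b = (1 - mean) * nu)
}

other_bases <- function(ref) {
  bases <- c("A", "C", "G", "T")
  vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
         USE.NAMES = FALSE)
}

#' Simulate the diploid germline truth set and panel regions
#'
#' Draws a random reference sequence for one synthetic chromosome, defines
#' the panel (the whole chromosome), a low-complexity tail, and the CTR as
#' a leading fraction of the panel, then places `n_het` + `n_hom` germline
#' variants uniformly over the assessable bases. Deterministic given
#' `truth_seed` (the RNG seed is set inside).
#'
#' @param config a [sim_config].
#' @param panel_name label for the simulated panel.
#' @return A `sim_truth` object: reference sequence, `panel`, `ctr`,
#'   `low_complexity` and `effective` RegionSets, a [panel_config], the
#'   truth variant data frame (with `genotype_vaf`, `zygosity`, `key`),
#'   and the C/G and A/T position pools used for artifact and noise
#'   placement.
#' @export
simulate_truth <- function(config, panel_name = "panelA") {
  set.seed(config$truth_seed)
  L <- as.integer(config$panel_size_bases)
  ref_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  chrom <- "chr1"
  lc_start <- floor(L * (1 - config$low_complexity_fraction))
  panel <- region_set(chrom, 0, L, label = paste0(panel_name, "_target"))
  low_complexity <- if (lc_start < L) {
    region_set(chrom, lc_start, L, label = "low_complexity")
  } else {
    region_set(label = "low_complexity")
  }
  ctr_end <- floor(config$ctr_fraction * L)
  ctr <- region_set(chrom, 0, ctr_end, label = "CTR")
  n_t <- config$n_het + config$n_hom
  if (n_t > lc_start) stop("truth variants exceed assessable panel bases")
  pos <- sort(sample.int(lc_start, n_t))
  zyg <- sample(c(rep("HET", config$n_het), rep("HOM", config$n_hom)))
  refb <- ref_chars[pos]
  truth <- data.frame(
    chrom = chrom, pos = pos, ref = refb, alt = other_bases(refb),
    genotype_vaf = ifelse(zyg == "HET", 0.5, 1.0), zygosity = zyg,
    stringsAsFactors = FALSE
  )
  truth$key <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
  idx <- seq_len(lc_start)
  cg_pool <- setdiff(idx[ref_chars[idx] %in% c("C", "G")], pos)
  at_pool <- setdiff(idx[ref_chars[idx] %in% c("A", "T")], pos)
  panel_cfg <- panel_config(panel_name, panel, low_complexity,
                            config$default_vaf_threshold)
  structure(list(
    panel_name = panel_name, chrom = chrom,
    reference = stats::setNames(paste(ref_chars, collapse = ""), chrom),
    panel = panel, low_complexity = low_complexity,
    effective = panel_cfg$effective_region, ctr = ctr,
    panel_cfg = panel_cfg, truth = truth,
    cg_pool = cg_pool, at_pool = at_pool
  ), class = "sim_truth")
}

#' Simulate a second (contaminating) genome
#'
#' An independent diploid individual on the same reference: its own
#' het/hom variant set at fresh positions, plus — for each host homozygous
#' site — whether the contaminant shares the allele (it does not with
#' probability `contaminant_mismatch_frac`). Uses the current RNG stream.
#'
#' @param truth a `sim_truth`.
#' @param config the [sim_config].
#' @return List with `variants` (data frame like the truth set) and
#'   `hom_match` (logical, named by host homozygous keys).
#' @export
simulate_second_genome <- function(truth, config) {
  lc_start <- max(c(truth$cg_pool, truth$at_pool))
  avail <- setdiff(seq_len(lc_start), truth$truth$pos)
  n_t <- config$n_het + config$n_hom
  pos <- sort(sample(avail, n_t))
  ref_chars <- strsplit(truth$reference[[1]], "")[[1]]
  refb <- ref_chars[pos]
  zyg <- sample(c(rep("HET", config$n_het), rep("HOM", config$n_hom)))
  variants <- data.frame(
    chrom = truth$chrom, pos = pos, ref = refb, alt = other_bases(refb),
    genotype_vaf = ifelse(zyg == "HET", 0.5, 1.0), zygosity = zyg,
    stringsAsFactors = FALSE
  )
  variants$key <- paste(variants$chrom, variants$pos, variants$ref,
                        variants$alt, sep = ":")
  hom_keys <- truth$truth$key[truth$truth$zygosity == "HOM"]
  hom_match <- stats::setNames(
    stats::runif(length(hom_keys)) >= config$contaminant_mismatch_frac,
    hom_keys
  )
  list(variants = variants, hom_match = hom_match)
}

#' Draw a synthetic germline database
#'
#' Contaminant variants are included with probability `germline_db_prob`,
#' mimicking the (high but incomplete) database coverage of real germline
#' polymorphisms.
#'
#' @param second_genome output of [simulate_second_genome].
#' @param config the [sim_config].
#' @return Character vector of database variant keys.
#' @export
simulate_germline_db <- function(second_genome, config) {
  keys <- second_genome$variants$key
  keys[stats::runif(length(keys)) < config$germline_db_prob]
}

#' Simulate the cell-count profile of one FFPE block
#'
#' Inner sections draw counts around the inner mean; the outermost
#' sections are scaled down by the surface factors, reproducing the
#' edge-effect cellularity drop. Flanking H&E slide counts are emitted so
#' [estimate_cell_count] applies; the generator's true position labels are
#' recorded for recovery tests.
#'
#' @param config a [sim_config].
#' @param block block letter.
#' @param fixation_hours fixation time of the block.
#' @return Data frame: block, fixation_hours, position, flank counts,
#'   cell_count, true_category.
#' @export
simulate_block <- function(config, block = "G", fixation_hours = 6) {
  n <- config$sections_per_block
  base <- stats::rnorm(n, config$inner_cell_mean,
                       config$inner_cell_cv * config$inner_cell_mean)
  fac <- rep(1, n)
  cat_true <- rep("INNER", n)
  s1 <- config$surface1_sections
  s2 <- config$surface2_sections
  if (s1 > 0) {
    ends <- c(seq_len(s1), seq(n - s1 + 1, n))
    fac[ends] <- config$surface1_factor
    cat_true[ends] <- "SURFACE_1"
  }
  if (s2 > 0) {
    mids <- c(seq(s1 + 1, s1 + s2), seq(n - s1 - s2 + 1, n - s1))
    fac[mids] <- config$surface2_factor
    cat_true[mids] <- "SURFACE_2"
  }
  target <- pmax(0, base * fac)
  flank_a <- pmax(0, round(target / 4 * stats::runif(n, 0.95, 1.05)))
  flank_b <- pmax(0, round(target / 4 * stats::runif(n, 0.95, 1.05)))
  data.frame(
    block = block, fixation_hours = fixation_hours, position = seq_len(n),
    flank_count_a = flank_a, flank_count_b = flank_b,
    cell_count = estimate_cell_count(flank_a, flank_b),
    true_category = cat_true, stringsAsFactors = FALSE
  )
}

#' Simulate one sample's variant calls
#'
#' Emits the raw (pre-cleaning) call list of one section:
#' \itemize{
#'   \item germline truth variants with Gaussian VAF noise (clipped to
#'     \[0, 1\]); under contamination at fraction `f`, host homozygous
#'     sites the contaminant does not share shift to VAF `1 - f`, and the
#'     contaminant's own variants appear around VAF `f/2` and `f`;
#'   \item Poisson-distributed deamination artifacts (C>T / G>A, placed on
#'     C/G reference positions) at the inner rate times the surface
#'     multiplier for surface sections — and, by default, independent of
#'     fixation time;
#'   \item sporadic noise calls with OTHER-type substitutions at A/T
#'     positions.
#' }
#' Every emitted row is tagged with its `origin`
#' (truth/artifact/contaminant/noise), the ground truth for recovery
#' tests. Uses the current RNG stream.
#'
#' @param truth a `sim_truth`.
#' @param config the [sim_config].
#' @param sample_id sample identifier.
#' @param position_category `"INNER"`, `"SURFACE_1"`, `"SURFACE_2"`, or
#'   `"FRESH"` (no FFPE artifacts).
#' @param fixation_hours fixation time (only relevant when a nonzero
#'   `fixation_effect_per_hour` is configured).
#' @param contamination_fraction admixture fraction in \[0, 0.5).
#' @param second_genome required when `contamination_fraction > 0`.
#' @return Variant data frame with an `origin` column.
#' @export
simulate_sample <- function(truth, config, sample_id = "S1",
                            position_category = "INNER", fixation_hours = 6,
                            contamination_fraction = 0, second_genome = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  f <- contamination_fraction
  if (f > 0 && is.null(second_genome)) {
    stop("contamination requested without a second genome")
  }
  eff_mb <- total_bases(truth$effective) / 1e6
  is_surface <- position_category %in% c("SURFACE_1", "SURFACE_2")
  rate <- if (position_category == "FRESH") 0 else {
    config$deamination_rate_inner_per_mb *
      (1 + config$fixation_effect_per_hour * fixation_hours) *
      (if (is_surface) config$surface_multiplier else 1)
  }

  tv <- truth$truth
  vaf <- tv$genotype_vaf + stats::rnorm(nrow(tv), 0, config$vaf_noise_sd)
  if (f > 0) {
    mism_keys <- names(second_genome$hom_match)[!second_genome$hom_match]
    shift <- tv$key %in% mism_keys
    vaf[shift] <- 1 - f + stats::rnorm(sum(shift), 0, config$vaf_noise_sd)
  }
  parts <- list(data.frame(
    chrom = tv$chrom, pos = tv$pos, ref = tv$ref, alt = tv$alt,
    vaf = pmin(pmax(vaf, 0), 1), origin = "truth", stringsAsFactors = FALSE
  ))

  if (f > 0) {
    cv <- second_genome$variants
    cvaf <- f * cv$genotype_vaf + stats::rnorm(nrow(cv), 0, config$vaf_noise_sd)
    keep <- cvaf > 0
    parts$contaminant <- data.frame(
      chrom = cv$chrom[keep], pos = cv$pos[keep], ref = cv$ref[keep],
      alt = cv$alt[keep], vaf = pmin(cvaf[keep], 1), origin = "contaminant",
      stringsAsFactors = FALSE
    )
  }

  k <- stats::rpois(1, rate * eff_mb)
  if (k > 0) {
    apos <- sample(truth$cg_pool, k)
    aref <- substring(truth$reference[[1]], apos, apos)
    sh <- beta_shapes(config$artifact_vaf_mean, config$artifact_vaf_sd)
    parts$artifact <- data.frame(
      chrom = truth$chrom, pos = apos, ref = aref,
      alt = ifelse(aref == "C", "T", "A"),
      vaf = stats::rbeta(k, sh[["a"]], sh[["b"]]), origin = "artifact",
      stringsAsFactors = FALSE
    )
  }

  k2 <- stats::rpois(1, config$noise_rate_per_mb * eff_mb)
  if (k2 > 0) {
    npos <- sample(truth$at_pool, k2)
    nref <- substring(truth$reference[[1]], npos, npos)
    parts$noise <- data.frame(
      chrom = truth$chrom, pos = npos, ref = nref, alt = other_bases(nref),
      vaf = stats::rbeta(k2, config$noise_vaf_shape[1], config$noise_vaf_shape[2]),
      origin = "noise", stringsAsFactors = FALSE
    )
  }

  df <- do.call(rbind, parts)
  key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  df <- df[!duplicated(key), , drop = FALSE] # origin priority: listed order
  dp <- pmax(100, round(stats::rnorm(nrow(df), config$depth_mean, config$depth_sd)))
  df$total_depth <- dp
  df$alt_depth <- pmin(dp, round(df$vaf * dp))
  df$sample_id <- sample_id
  df <- df[order(df$pos, df$ref, df$alt),
           c(variant_columns, "origin")]
  rownames(df) <- NULL
  df
}

#' Simulate replicate reference (fresh DNA) samples
#'
#' Fresh genomic DNA replicates: truth variants plus sporadic noise, no
#' FFPE artifacts — the cohort a known-variant set is built from.
#'
#' @param truth a `sim_truth`.
#' @param config the [sim_config].
#' @param n number of replicates.
#' @param prefix sample-id prefix.
#' @return Named list of variant data frames.
#' @export
simulate_reference_samples <- function(truth, config, n = 12,
                                       prefix = "FRESH") {
  ids <- sprintf("%s_%02d", prefix, seq_len(n))
  stats::setNames(lapply(ids, function(id) {
    simulate_sample(truth, config, sample_id = id,
                    position_category = "FRESH")
  }), ids)
}

#' Simulate a complete multi-panel study cohort
#'
#' Eight blocks (two per fixation time) are sectioned, every panel draws
#' `samples_per_block` sections evenly from each block (disjoint positions
#' across panels, as physical sections go to one laboratory each), and
#' each drawn section is sequenced in silico on its panel. Sample ids use
#' the `fixation_block_position` coding. Optionally contaminated samples
#' are mixed with a per-panel second genome, and the matching synthetic
#' germline database is emitted. Fully reproducible from `seed` /
#' `truth_seed`; with the default four panels of three sections per block
#' the cohort holds 96 sequenced sections.
#'
#' @param config a [sim_config].
#' @param dir optional directory; when given, per-sample VCFs, the
#'   reference FASTA, panel/CTR/low-complexity BEDs, metadata and truth
#'   TSVs and the configuration (JSON) are written beneath it.
#' @return A `sim_cohort`: `config`, `metadata` (one row per panel x
#'   sample, with true position categories and expected artifact means),
#'   and `panels` — per panel the `sim_truth`, the drawn samples (variant
#'   frames with `origin`), the second genome and germline-database keys.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  panel_names <- paste0("panel", LETTERS[seq_len(config$n_panels)])
  truths <- lapply(seq_along(panel_names), function(p) {
    cfg_p <- config
    cfg_p$truth_seed <- config$truth_seed + p - 1
    simulate_truth(cfg_p, panel_name = panel_names[p])
  })
  names(truths) <- panel_names

  set.seed(config$seed)
  blocks <- do.call(rbind, unlist(lapply(config$fixation_times, function(ft) {
    lapply(c("G", "H"), function(b) simulate_block(config, b, ft))
  }), recursive = FALSE))

  n_sec <- config$sections_per_block
  contam <- config$contamination_fractions
  panels <- list()
  metadata <- list()
  for (p in seq_along(panel_names)) {
    pn <- panel_names[p]
    truth <- truths[[p]]
    eff_mb <- total_bases(truth$effective) / 1e6
    draw_pos <- round(seq(p, n_sec - (config$n_panels - p),
                          length.out = config$samples_per_block))
    sec <- blocks[blocks$position %in% draw_pos, , drop = FALSE]
    sec$sample_id <- paste(sec$fixation_hours, sec$block, sec$position, sep = "_")
    second <- simulate_second_genome(truth, config)
    db <- simulate_germline_db(second, config)
    samples <- list()
    for (i in seq_len(nrow(sec))) {
      sid <- sec$sample_id[i]
      f <- if (!is.null(contam) && sid %in% names(contam)) contam[[sid]] else 0
      samples[[sid]] <- simulate_sample(
        truth, config, sample_id = sid,
        position_category = sec$true_category[i],
        fixation_hours = sec$fixation_hours[i],
        contamination_fraction = f,
        second_genome = if (f > 0) second else NULL
      )
    }
    is_surf <- sec$true_category != "INNER"
    sec$panel <- pn
    sec$contamination_fraction <-
      if (is.null(contam)) 0 else ifelse(sec$sample_id %in% names(contam),
                                         contam[match(sec$sample_id, names(contam))], 0)
    sec$expected_gc_to_at <- config$deamination_rate_inner_per_mb * eff_mb *
      (1 + config$fixation_effect_per_hour * sec$fixation_hours) *
      ifelse(is_surf, config$surface_multiplier, 1)
    sec$dna_yield_ng <- round(sec$cell_count * 0.0066 *
                                stats::rlnorm(nrow(sec), 0, 0.2), 1)
    sec$library_yield <- round(pmax(1, stats::rnorm(nrow(sec), 120, 20)), 1)
    sec$median_dedup_depth <- round(stats::rnorm(nrow(sec), 2000, 150))
    sec$library_complexity <- round(stats::rnorm(nrow(sec), 5e5, 5e4))
    sec$experiment_failed <- FALSE
    metadata[[pn]] <- sec
    panels[[pn]] <- list(truth = truth, samples = samples,
                         second_genome = second, germline_db = db)
  }
  metadata <- do.call(rbind, metadata)
  rownames(metadata) <- NULL
  cohort <- structure(list(config = config, metadata = metadata,
                           panels = panels), class = "sim_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d panel(s), %d sequenced sections, %s-base panels\n",
              length(x$panels), nrow(x$metadata),
              format(x$config$panel_size_bases, big.mark = ",")))
  invisible(x)
}

# write a simulated cohort to disk as VCF/FASTA/BED/TSV
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pn in names(cohort$panels)) {
    pd <- file.path(dir, pn)
    dir.create(pd, showWarnings = FALSE)
    truth <- cohort$panels[[pn]]$truth
    ss <- Biostrings::DNAStringSet(truth$reference)
    Biostrings::writeXStringSet(ss, file.path(pd, "reference.fa"))
    write_bed(truth$panel, file.path(pd, "target.bed"))
    write_bed(truth$low_complexity, file.path(pd, "low_complexity.bed"))
    write_bed(truth$ctr, file.path(pd, "ctr.bed"))
    utils::write.table(truth$truth, file.path(pd, "truth_variants.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(cohort$panels[[pn]]$germline_db,
               file.path(pd, "germline_db_keys.txt"))
    origins <- do.call(rbind, lapply(cohort$panels[[pn]]$samples, function(s) {
      data.frame(sample_id = s$sample_id, key = variant_key(s),
                 origin = s$origin, stringsAsFactors = FALSE)
    }))
    utils::write.table(origins, file.path(pd, "origins.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    for (s in cohort$panels[[pn]]$samples) {
      write_variants_vcf(s, file.path(pd, paste0(s$sample_id[1], ".vcf")))
    }
  }
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  writeLines(
    paste(names(cfg),
          vapply(cfg, function(v) paste(format(v, scientific = FALSE), collapse = ","),
                 character(1)),
          sep = "\t"),
    file.path(dir, "config.tsv")
  )
  invisible(dir)
}

#' Closed-form expectation of the contamination tail statistic
#'
#' Under the generator's mixing rule, a fraction `h` of the homozygous
#' cluster sits at VAF `1 - f` with Gaussian noise of sd `sd`; the 95th
#' percentile of `1 - VAF` over the cluster then falls inside that
#' displaced component at `f + qnorm(1 - 0.05/h) * sd` (valid for
#' `h > 0.05`, i.e. when the displaced component carries the tail).
#'
#' @param f contamination fraction.
#' @param h contaminant mismatch fraction at homozygous sites.
#' @param sd VAF noise standard deviation.
#' @return Expected [vaf_tail_statistic].
#' @export
expected_tail_statistic <- function(f, h, sd) {
  if (h <= 0.05) stop("closed form requires h > 0.05")
  f + stats::qnorm(1 - 0.05 / h) * sd
}
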