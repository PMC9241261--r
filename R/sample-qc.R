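#' Parse the study-style sample identifier
#'
#' Samples are coded `fixationHours_Block_Position` (e.g. `6_G_7`): formalin
#' fixation time in hours, FFPE block letter, and section position within
#' the block.
#'
#' @param id character vector of sample identifiers.
#' @return Data frame with `sample_id`, `fixation_hours` (integer), `block`
#'   (uppercase letter) and `position` (integer).
#' @export
parse_sample_id <- function(id) {
  parts <- strsplit(as.character(id), "_", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) {
    stop("sample_id '", id[which(bad)[1]],
         "' does not parse as fixation_block_position")
  }
  fix <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
  block <- vapply(parts, `[[`, "", 2)
  posn <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  if (any(is.na(fix)) || any(is.na(posn)) || any(!grepl("^[A-Z]$", block))) {
    stop("sample_id fields must be <hours>_<BLOCK LETTER>_<position>")
  }
  data.frame(sample_id = as.character(id), fixation_hours = fix,
             block = block, position = posn, stringsAsFactors = FALSE)
}

#' Estimate the cell count of a curl-set tube
#'
#' The tube's cellularity is estimated from the two flanking H&E slides:
#' their average count times four (a 10–20 um lymphoblast appears in about
#' two adjacent 5 um sections, and a tube holds eight sections).
#'
#' @param flank_count_a,flank_count_b cell counts of the two flanking H&E
#'   slides (vectorized, non-negative).
#' @return Integer estimate: `round(4 * mean(a, b))`.
#' @export
estimate_cell_count <- function(flank_count_a, flank_count_b) {
  if (any(flank_count_a < 0) || any(flank_count_b < 0)) {
    stop("cell counts must be non-negative")
  }
  round(4 * (flank_count_a + flank_count_b) / 2)
}

#' Categorize block sections into surface and inner positions
#'
#' Mirrors the sectioning rules of FFPE cell blocks, where the outermost
#' ("edge-effect") sections show depressed cellularity:
#' \itemize{
#'   \item `SURFACE_1`: consecutive end sections whose cell count is below
#'     50\% of the block-wide mean;
#'   \item `SURFACE_2`: the next three adjacent sections at each end,
#'     extended by one or two further sections when their counts are closer
#'     (absolute difference) to the mean `SURFACE_1` count than to the mean
#'     of the provisional inner sections;
#'   \item `INNER`: everything else.
#' }
#' The rule is applied symmetrically at both ends, so labels are invariant
#' under reversing the position order.
#'
#' @param positions integer section positions (depth order).
#' @param counts cell-count estimates, parallel to `positions`.
#' @return Character vector of labels named by position, in the input order.
#' @export
categorize_positions <- function(positions, counts) {
  if (length(positions) == 0) stop("no positions supplied")
  stopifnot(length(positions) == length(counts))
  ord <- order(positions)
  pos <- positions[ord]
  cnt <- counts[ord]
  n <- length(pos)
  lab <- rep(NA_character_, n)
  overall_mean <- mean(cnt)

  # SURFACE_1: consecutive runs below 50% of the mean at each end
  s1_left <- 0
  while (s1_left < n && cnt[s1_left + 1] < 0.5 * overall_mean) s1_left <- s1_left + 1
  s1_right <- 0
  while (s1_right < n - s1_left && cnt[n - s1_right] < 0.5 * overall_mean) {
    s1_right <- s1_right + 1
  }
  if (s1_left > 0) lab[seq_len(s1_left)] <- "SURFACE_1"
  if (s1_right > 0) lab[seq(n - s1_right + 1, n)] <- "SURFACE_1"

  # SURFACE_2: next three adjacent sections at each end
  unassigned <- which(is.na(lab))
  take_left <- utils::head(unassigned, 3)
  take_right <- utils::tail(setdiff(unassigned, take_left), 3)
  lab[c(take_left, take_right)] <- "SURFACE_2"

  # extension: up to two more per end if much closer to the surface counts
  for (side in c("left", "right")) {
    s1_idx <- if (side == "left") seq_len(s1_left) else
      if (s1_right > 0) seq(n - s1_right + 1, n) else integer(0)
    if (length(s1_idx) == 0) next # no SURFACE_1 at this end: no extension
    s1_mean <- mean(cnt[s1_idx])
    for (k in 1:2) {
      unassigned <- which(is.na(lab))
      if (length(unassigned) <= 1) break
      cand <- if (side == "left") unassigned[1] else unassigned[length(unassigned)]
      inner_mean <- mean(cnt[setdiff(unassigned, cand)])
      if (abs(cnt[cand] - s1_mean) < abs(cnt[cand] - inner_mean)) {
        lab[cand] <- "SURFACE_2"
      } else {
        break
      }
    }
  }
  lab[is.na(lab)] <- "INNER"
  out <- lab[order(ord)]
  names(out) <- as.character(positions)
  out
}

#' VAF-histogram tail statistic for contamination detection
#'
#' Homozygous germline variants of a pure diploid sample sit at VAF 1.0;
#' admixed DNA from a second individual displaces part of that cluster
#' leftward. The statistic is the 95th percentile of `1 - VAF` over the
#' homozygous cluster (calls with VAF above `hom_cutoff`) — a scale-free
#' measure of how far the tail extends from 100\%.
#'
#' @param vafs VAFs of a sample's cleaned calls.
#' @param hom_cutoff lower VAF bound of the homozygous cluster (default 0.7).
#' @param min_hom minimum cluster size for the statistic to be defined
#'   (default 10); below it `NA` is returned with a warning.
#' @return The tail statistic, or `NA_real_` when undefined.
#' @export
vaf_tail_statistic <- function(vafs, hom_cutoff = 0.7, min_hom = 10) {
  hv <- vafs[!is.na(vafs) & vafs > hom_cutoff]
  if (length(hv) < min_hom) {
    warning("fewer than ", min_hom, " calls above VAF ", hom_cutoff,
            "; tail statistic undefined")
    return(NA_real_)
  }
  unname(stats::quantile(1 - hv, 0.95))
}

#' Fraction of false-positive calls found in a germline database
#'
#' Contamination is confirmed when a suspect sample's FP calls are largely
#' known germline polymorphisms (dbSNP/ExAC-style database): true FFPE
#' artifacts are not expected there, a second individual's genome is.
#'
#' @param fp_keys variant keys of the sample's FP calls.
#' @param germline_db character vector of database variant keys.
#' @return `|fp ∩ db| / |fp|`, or 0 when there are no FP calls.
#' @export
germline_overlap_fraction <- function(fp_keys, germline_db) {
  if (length(fp_keys) == 0) return(0)
  mean(fp_keys %in% germline_db)
}

#' QC thresholds
#'
#' Collects the numeric thresholds of the five QC checks plus the
#' contamination-detector settings. Studies anchor these differently per
#' panel (e.g. a median deduplicated depth of 850, a library QC threshold
#' of 50 pM, surface cell counts below 10,000); all are plain inputs here.
#'
#' @param min_cell_count minimum estimated cells per section.
#' @param min_dna_input_ng minimum DNA yield for library preparation (ng).
#' @param min_library_yield minimum library yield (panel-specific units).
#' @param min_median_dedup_depth minimum median deduplicated depth.
#' @param tail_multiplier a sample is suspect when its VAF tail statistic
#'   exceeds this multiple of the cohort median ("several times wider").
#' @param overlap_min minimum germline-database overlap fraction of the FP
#'   calls required to confirm contamination.
#' @return A `QCThresholds` list.
#' @export
qc_thresholds <- function(min_cell_count = 10000, min_dna_input_ng = 20,
                          min_library_yield = 50,
                          min_median_dedup_depth = 850,
                          tail_multiplier = 3, overlap_min = 0.5) {
  vals <- c(min_cell_count, min_dna_input_ng, min_library_yield,
            min_median_dedup_depth, tail_multiplier, overlap_min)
  if (any(vals < 0)) stop("QC thresholds must be non-negative")
  structure(list(min_cell_count = min_cell_count,
                 min_dna_input_ng = min_dna_input_ng,
                 min_library_yield = min_library_yield,
                 min_median_dedup_depth = min_median_dedup_depth,
                 tail_multiplier = tail_multiplier,
                 overlap_min = overlap_min), class = "QCThresholds")
}

#' Flag a sample as contaminated
#'
#' Two-stage detect-then-confirm rule: the sample's VAF tail statistic must
#' exceed `tail_multiplier` times the cohort median (detection), and the
#' fraction of its FP calls found in the germline database must exceed
#' `overlap_min` (confirmation). A wide tail alone — pure noise — is not
#' flagged, and neither is database overlap without a tail.
#'
#' @param tail_stat the sample's [vaf_tail_statistic].
#' @param cohort_tails tail statistics of the cohort (>= 4 non-missing).
#' @param overlap the sample's [germline_overlap_fraction].
#' @param thresholds a [qc_thresholds] object.
#' @return Logical flag.
#' @export
flag_contamination <- function(tail_stat, cohort_tails, overlap,
                               thresholds = qc_thresholds()) {
  ct <- cohort_tails[!is.na(cohort_tails)]
  if (length(ct) < 4) stop("need tail statistics from at least 4 cohort samples")
  if (is.na(tail_stat)) return(FALSE)
  med <- stats::median(ct)
  (tail_stat > thresholds$tail_multiplier * med) &&
    (overlap > thresholds$overlap_min)
}

qc_groups <- c("PASS_INNER", "FAIL_INNER", "SURFACE", "EXCLUDED")

#' Assign a sample to its analysis group
#'
#' The three analysis groups are QC-passed inner, QC-failed inner, and
#' surface FFPE samples. A sample is `EXCLUDED` only for failures unrelated
#' to FFPE processing itself: an explicit experiment failure (library
#' failed, not sequenced) or detected contamination. Position dominates QC:
#' a surface sample is `SURFACE` whether or not it meets the thresholds,
#' while inner samples split into `PASS_INNER` / `FAIL_INNER` on the
#' numeric checks. QC-threshold failures alone never exclude.
#'
#' @param sample a list or one-row data frame with `cell_count`,
#'   `dna_yield_ng`, `library_yield`, `median_dedup_depth`.
#' @param position_category `"SURFACE_1"`, `"SURFACE_2"`, `"INNER"` (or
#'   `"FRESH"` for non-FFPE reference samples, which pass straight to the
#'   threshold checks).
#' @param thresholds a [qc_thresholds] object.
#' @param experiment_failed explicit metadata flag for failures upstream of
#'   analysis.
#' @param contamination_flag result of [flag_contamination].
#' @return One of `"PASS_INNER"`, `"FAIL_INNER"`, `"SURFACE"`, `"EXCLUDED"`.
#' @export
qc_classify <- function(sample, position_category,
                        thresholds = qc_thresholds(),
                        experiment_failed = FALSE,
                        contamination_flag = FALSE) {
  if (isTRUE(experiment_failed) || isTRUE(contamination_flag)) {
    return("EXCLUDED")
  }
  if (position_category %in% c("SURFACE_1", "SURFACE_2")) return("SURFACE")
  needed <- c("cell_count", "dna_yield_ng", "library_yield", "median_dedup_depth")
  for (f in needed) {
    v <- sample[[f]]
    if (is.null(v) || length(v) == 0 || is.na(v)) {
      stop("missing required QC field '", f, "'")
    }
  }
  pass <- sample[["cell_count"]] >= thresholds$min_cell_count &&
    sample[["dna_yield_ng"]] >= thresholds$min_dna_input_ng &&
    sample[["library_yield"]] >= thresholds$min_library_yield &&
    sample[["median_dedup_depth"]] >= thresholds$min_median_dedup_depth
  if (pass) "PASS_INNER" else "FAIL_INNER"
}

#' Classify every sample of a metadata table
#'
#' Vectorized convenience over [qc_classify]. The metadata must carry a
#' `position_category` column (e.g. from [categorize_positions] applied per
#' block) plus the QC measurement columns; `experiment_failed` and
#' `contamination_flag` columns are optional and default to `FALSE`.
#'
#' @param metadata sample metadata data frame.
#' @param thresholds a [qc_thresholds] object.
#' @return The metadata with a `group` column appended.
#' @export
classify_samples <- function(metadata, thresholds = qc_thresholds()) {
  ef <- if ("experiment_failed" %in% names(metadata)) metadata$experiment_failed else FALSE
  cf <- if ("contamination_flag" %in% names(metadata)) metadata$contamination_flag else FALSE
  ef <- rep_len(ef, nrow(metadata))
  cf <- rep_len(cf, nrow(metadata))
  metadata$group <- vapply(seq_len(nrow(metadata)), function(i) {
    qc_classify(metadata[i, , drop = FALSE], metadata$position_category[i],
                thresholds, ef[i], cf[i])
  }, character(1))
  metadata
}

#' Read a sample metadata TSV
#'
#' Expects columns `sample_id` plus the QC measurements; `fixation_hours`,
#' `block` and `position` are derived from the sample id when absent, and
#' `cell_count` from `flank_count_a`/`flank_count_b` when absent.
#'
#' @param path TSV path.
#' @return Metadata data frame.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata must have a sample_id column")
  if (!all(c("fixation_hours", "block", "position") %in% names(md))) {
    parsed <- parse_sample_id(md$sample_id)
    md <- cbind(md[setdiff(names(md), names(parsed))], parsed)
  }
  if (!"cell_count" %in% names(md) &&
      all(c("flank_count_a", "flank_count_b") %in% names(md))) {
    md$cell_count <- estimate_cell_count(md$flank_count_a, md$flank_count_b)
  }
  md
}
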