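damage_types <- c("INDEL", "GC_TO_AT", "GC_TO_TA", "OTHER")

#' Classify the FFPE damage type of a variant
#'
#' Partitions calls into the four categories used to read out FFPE damage:
#' \describe{
#'   \item{INDEL}{allele lengths differ}
#'   \item{GC_TO_AT}{C>T or G>A — hydrolytic (cytosine) deamination
#'     transitions, the signature of formalin fixation damage}
#'   \item{GC_TO_TA}{C>A or G>T — oxidative damage (8-oxoG) transversions}
#'   \item{OTHER}{any other substitution}
#' }
#' Classification is on the normalized, decomposed representation, so an
#' MNV contributes its per-base SNVs.
#'
#' @param ref,alt normalized allele strings (vectorized).
#' @return Character vector of damage types.
#' @export
classify_damage_type <- function(ref, alt) {
  out <- rep("OTHER", length(ref))
  out[nchar(ref) != nchar(alt)] <- "INDEL"
  snv <- nchar(ref) == 1 & nchar(alt) == 1
  out[snv & ((ref == "C" & alt == "T") | (ref == "G" & alt == "A"))] <- "GC_TO_AT"
  out[snv & ((ref == "C" & alt == "A") | (ref == "G" & alt == "T"))] <- "GC_TO_TA"
  out
}

scope_region <- function(panel, ctr, scope) {
  switch(scope,
    whole_panel = panel$effective_region,
    in_ctr = {
      if (is.null(ctr)) stop("scope '", scope, "' requires a CTR")
      region_intersect(panel$effective_region, ctr)
    },
    out_ctr = {
      if (is.null(ctr)) stop("scope '", scope, "' requires a CTR")
      region_subtract(panel$effective_region, ctr)
    },
    stop("unknown scope: ", scope)
  )
}

#' Identify and classify false-positive calls for one sample
#'
#' Every cleaned call whose normalized key is absent from the panel's known
#' variant set is a false positive. Calls and known variants are first
#' restricted to the requested region scope (`whole_panel` = the panel's
#' assessable bases, `in_ctr` = their intersection with the CTR, `out_ctr`
#' = the remainder). The FP rate is reported per million scope bases, and
#' sensitivity is the fraction of in-scope known variants recovered by the
#' sample.
#'
#' @param sample cleaned variant data frame.
#' @param known `KnownVariantSet` (or character vector of known keys).
#' @param panel [panel_config] providing the assessable region.
#' @param ctr `RegionSet`, required for the CTR scopes.
#' @param scope one of `"in_ctr"`, `"whole_panel"`, `"out_ctr"`.
#' @return An `fp_report`: list with `sample_id`, `scope`, `fp_calls` (the
#'   FP rows plus a `damage_type` column), `fp_count`,
#'   `region_size_bases`, `fpr_per_million`, `type_counts` and
#'   `sensitivity`.
#' @export
call_false_positives <- function(sample, known, panel, ctr = NULL,
                                 scope = c("in_ctr", "whole_panel", "out_ctr")) {
  scope <- match.arg(scope)
  validate_variants(sample)
  region <- scope_region(panel, ctr, scope)
  size <- total_bases(region)
  if (size == 0) stop("scope '", scope, "' has zero assessable bases")

  in_scope <- sample[region_contains(region, sample$chrom, sample$pos), , drop = FALSE]
  keys <- variant_key(in_scope)

  if (inherits(known, "KnownVariantSet")) {
    ke <- known$entries
    known_in_scope <- ke$key[region_contains(region, ke$chrom, ke$pos)]
  } else {
    known_in_scope <- as.character(known)
  }

  fp <- in_scope[!(keys %in% known_in_scope), , drop = FALSE]
  fp$damage_type <- classify_damage_type(fp$ref, fp$alt)
  rownames(fp) <- NULL
  type_counts <- table(factor(fp$damage_type, levels = damage_types))
  sensitivity <- if (length(known_in_scope) == 0) {
    NA_real_
  } else {
    sum(known_in_scope %in% keys) / length(known_in_scope)
  }
  structure(list(
    sample_id = if (nrow(sample) > 0) sample$sample_id[1] else NA_character_,
    scope = scope,
    fp_calls = fp,
    fp_count = nrow(fp),
    region_size_bases = size,
    fpr_per_million = nrow(fp) / size * 1e6,
    type_counts = stats::setNames(as.integer(type_counts), damage_types),
    sensitivity = sensitivity
  ), class = "fp_report")
}

#' @export
print.fp_report <- function(x, ...) {
  cat(sprintf("fp_report %s [%s]: %d FP in %s bases (%.3f per Mb), sensitivity %s\n",
              x$sample_id, x$scope, x$fp_count,
              format(x$region_size_bases, big.mark = ","), x$fpr_per_million,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.3f", x$sensitivity))))
  invisible(x)
}

#' One-row tidy summary of an fp_report
#'
#' @param x an `fp_report`.
#' @param ... ignored.
#' @return One-row data frame: sample_id, scope, fp_count,
#'   region_size_bases, fpr_per_million, per-type counts and sensitivity.
#' @export
as.data.frame.fp_report <- function(x, ...) {
  data.frame(
    sample_id = x$sample_id, scope = x$scope, fp_count = x$fp_count,
    region_size_bases = x$region_size_bases,
    fpr_per_million = x$fpr_per_million,
    n_indel = x$type_counts[["INDEL"]],
    n_gc_to_at = x$type_counts[["GC_TO_AT"]],
    n_gc_to_ta = x$type_counts[["GC_TO_TA"]],
    n_other = x$type_counts[["OTHER"]],
    sensitivity = x$sensitivity,
    stringsAsFactors = FALSE
  )
}

#' Bind a list of fp_reports into a tidy table
#'
#' @param reports list of `fp_report` objects.
#' @return Data frame, one row per report.
#' @export
fp_report_table <- function(reports) {
  do.call(rbind, lapply(reports, as.data.frame))
}

#' Normalized deamination score
#'
#' A sample's G:C>A:T count divided by the mean G:C>A:T count of a baseline
#' group (normally the QC-passed inner FFPE samples of the same panel).
#' When the primary baseline mean is zero — a panel whose QC-passed inner
#' samples show no deamination at all — the designated fallback group
#' (e.g. the fresh-DNA group) is used instead.
#'
#' @param sample_count G:C>A:T count(s) to normalize (vectorized).
#' @param baseline_group_counts counts of the primary baseline group.
#' @param fallback_group_counts optional fallback group counts, used only
#'   when `mean(baseline_group_counts) == 0`.
#' @return Numeric score(s): `sample_count / mean(baseline)`.
#' @export
normalized_deamination <- function(sample_count, baseline_group_counts,
                                   fallback_group_counts = NULL) {
  if (length(baseline_group_counts) == 0) stop("baseline group is empty")
  m <- mean(baseline_group_counts)
  if (m == 0) {
    if (!is.null(fallback_group_counts) && mean(fallback_group_counts) > 0) {
      m <- mean(fallback_group_counts)
    } else {
      stop("all candidate baseline groups have zero mean G:C>A:T count")
    }
  }
  sample_count / m
}

#' Sweep VAF and alt-depth cutoffs over a sample
#'
#' Re-filters the cleaned sample at every grid point (`vaf >= v` and
#' `alt_depth >= d`) and recomputes the FP report, tracing the
#' false-positive / sensitivity trade-off of more stringent post-call
#' filters. Both FP count and sensitivity are non-increasing along each
#' grid axis.
#'
#' @inheritParams call_false_positives
#' @param vaf_grid ascending VAF cutoffs (start it at the panel default to
#'   reproduce the unfiltered report at the first point).
#' @param alt_depth_grid ascending alternate-allele depth cutoffs.
#' @return Data frame: vaf_cutoff, ad_cutoff, fp_count, fpr_per_million,
#'   n_gc_to_at, sensitivity.
#' @export
cutoff_sweep <- function(sample, known, panel, ctr = NULL,
                         scope = c("in_ctr", "whole_panel", "out_ctr"),
                         vaf_grid = seq(panel$default_vaf_threshold, 0.10, by = 0.005),
                         alt_depth_grid = 0) {
  scope <- match.arg(scope)
  if (is.unsorted(vaf_grid) || is.unsorted(alt_depth_grid)) {
    stop("cutoff grids must be sorted ascending")
  }
  validate_variants(sample)
  grid <- expand.grid(vaf_cutoff = vaf_grid, ad_cutoff = alt_depth_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$vaf_cutoff[i]
    d <- grid$ad_cutoff[i]
    keep <- sample$vaf >= v &
      (if (d > 0) !is.na(sample$alt_depth) & sample$alt_depth >= d else TRUE)
    rep_ <- call_false_positives(sample[keep, , drop = FALSE], known, panel,
                                 ctr, scope)
    data.frame(vaf_cutoff = v, ad_cutoff = d, fp_count = rep_$fp_count,
               fpr_per_million = rep_$fpr_per_million,
               n_gc_to_at = rep_$type_counts[["GC_TO_AT"]],
               sensitivity = rep_$sensitivity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
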