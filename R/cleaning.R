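#' Clean a sample's variant list
#'
#' Applies the standard per-sample cleaning used throughout the pipeline:
#' keep only records inside the panel's assessable region (target minus
#' low-complexity), at or above the VAF threshold (inclusive), and not on
#' the panel blocklist; duplicate keys within the sample are collapsed to
#' the record of highest VAF. Input order is preserved.
#'
#' The input is assumed normalized and decomposed (see
#' [normalize_variants]); cleaning operates purely on keys, positions and
#' VAFs.
#'
#' @param raw variant data frame (normalized, atomic records).
#' @param panel a [panel_config] object.
#' @param vaf_threshold VAF cutoff; defaults to the panel's recommended
#'   threshold. Applied as `vaf >= vaf_threshold`.
#' @return Cleaned variant data frame.
#' @export
clean_sample <- function(raw, panel, vaf_threshold = NULL) {
  validate_variants(raw)
  stopifnot(inherits(panel, "PanelConfig"))
  if (is.null(vaf_threshold)) vaf_threshold <- panel$default_vaf_threshold
  if (nrow(raw) == 0) return(raw)
  keep <- region_contains(panel$effective_region, raw$chrom, raw$pos) &
    raw$vaf >= vaf_threshold &
    !(variant_key(raw) %in% panel$blocklist)
  out <- raw[keep, , drop = FALSE]
  if (nrow(out) > 1) {
    key <- variant_key(out)
    if (anyDuplicated(key)) {
      # collapse duplicates to the highest-VAF record, keeping first position
      best <- tapply(seq_len(nrow(out)), key, function(i) i[which.max(out$vaf[i])])
      out <- out[sort(unname(best)), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

known_set_keys <- function(known) {
  if (inherits(known, "KnownVariantSet")) known$entries$key else as.character(known)
}

#' Remove recurrent unknown indels from a cohort
#'
#' A platform-specific artifact can surface as the same false-positive indel
#' in many samples of one panel's cohort. This filter removes every indel
#' key that is absent from the known set and is called in at least
#' `min_samples` distinct samples; SNVs are never touched, however
#' recurrent.
#'
#' @param cohort named list of cleaned variant data frames (one per sample).
#' @param known a `KnownVariantSet` (or character vector of known keys).
#' @param min_samples minimum number of distinct samples sharing the indel
#'   for it to be removed; must be >= 2. The default 3 catches platform
#'   artifacts while leaving genuine singletons and doubletons alone.
#' @return `list(cohort = filtered cohort, removed_keys = character)`.
#' @export
recurrent_indel_filter <- function(cohort, known, min_samples = 3) {
  stopifnot(is.list(cohort), min_samples >= 2)
  kk <- known_set_keys(known)
  per_sample_keys <- lapply(cohort, function(df) {
    validate_variants(df)
    if (nrow(df) == 0) return(character(0))
    unique(variant_key(df)[is_indel(df$ref, df$alt)])
  })
  counts <- table(unlist(per_sample_keys, use.names = FALSE))
  candidates <- names(counts)[counts >= min_samples]
  removed <- setdiff(candidates, kk)
  filtered <- lapply(cohort, function(df) {
    if (nrow(df) == 0) return(df)
    out <- df[!(variant_key(df) %in% removed), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  list(cohort = filtered, removed_keys = removed)
}
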