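#' Classify zygosity of a germline variant from its VAF
#'
#' For a diploid sample, consensus variants cluster at VAF 0.5
#' (heterozygous) and 1.0 (homozygous). The classification uses 0.8 and 0.2
#' as the homozygous/heterozygous boundaries, with two additional low-VAF
#' bins split at 0.1:
#' `HOM` (vaf > 0.8), `HET` (0.2 < vaf <= 0.8), `LOW_HIGH`
#' (0.1 < vaf <= 0.2) and `LOW_LOW` (vaf <= 0.1).
#'
#' @param vaf numeric vector in \[0, 1\].
#' @return Character vector of bin labels.
#' @export
classify_zygosity <- function(vaf) {
  if (any(is.na(vaf)) || any(vaf < 0 | vaf > 1)) stop("vaf outside [0, 1]")
  out <- character(length(vaf))
  out[vaf > 0.8] <- "HOM"
  out[vaf > 0.2 & vaf <= 0.8] <- "HET"
  out[vaf > 0.1 & vaf <= 0.2] <- "LOW_HIGH"
  out[vaf <= 0.1] <- "LOW_LOW"
  out
}

zygosity_bins <- c("HOM", "HET", "LOW_HIGH", "LOW_LOW")

#' Build a consensus known-variant set from reference samples
#'
#' Aggregates cleaned variant lists from replicate reference samples
#' (typically fresh genomic DNA; for a panel lacking fresh replicates a
#' high-quality FFPE cohort can stand in — the builder is cohort-agnostic
#' and the caller chooses the roster). A variant becomes *known* when it is
#' called in strictly more than `fraction` of the reference samples
#' ("over 75%": with 12 samples this means at least 10). Each entry carries
#' the median VAF across supporting samples, the support count, its
#' zygosity bin, and whether it falls inside the CTR.
#'
#' @param reference_samples named list of cleaned variant data frames, one
#'   per reference sample (at least 2).
#' @param fraction support-fraction threshold in (0, 1); strict inequality.
#' @param ctr optional `RegionSet`; when supplied, each entry's `in_ctr`
#'   flag is computed by position membership.
#' @param panel panel name carried along for reporting.
#' @return A `KnownVariantSet`: list with `panel`, `n_reference_samples`,
#'   `fraction`, and `entries` (data frame: key, chrom, pos, ref, alt,
#'   median_vaf, support, n, zygosity, in_ctr).
#' @export
build_known_set <- function(reference_samples, fraction = 0.75, ctr = NULL,
                            panel = "") {
  if (!is.list(reference_samples) || length(reference_samples) == 0) {
    stop("reference_samples must be a non-empty list")
  }
  if (length(reference_samples) < 2) {
    stop("at least 2 reference samples are required")
  }
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- length(reference_samples)
  stacked <- do.call(rbind, lapply(reference_samples, function(df) {
    validate_variants(df)
    if (nrow(df) == 0) return(NULL)
    k <- variant_key(df)
    dup <- duplicated(k)
    data.frame(key = k[!dup], chrom = df$chrom[!dup], pos = df$pos[!dup],
               ref = df$ref[!dup], alt = df$alt[!dup], vaf = df$vaf[!dup],
               stringsAsFactors = FALSE)
  }))
  if (is.null(stacked) || nrow(stacked) == 0) {
    entries <- data.frame(key = character(), chrom = character(),
                          pos = numeric(), ref = character(),
                          alt = character(), median_vaf = numeric(),
                          support = integer(), n = integer(),
                          zygosity = character(), in_ctr = logical(),
                          stringsAsFactors = FALSE)
    return(structure(list(panel = panel, n_reference_samples = n,
                          fraction = fraction, entries = entries),
                     class = "KnownVariantSet"))
  }
  support <- tapply(stacked$vaf, stacked$key, length)
  med_vaf <- tapply(stacked$vaf, stacked$key, stats::median)
  keep_keys <- names(support)[support > fraction * n]
  first <- stacked[!duplicated(stacked$key), , drop = FALSE]
  rownames(first) <- first$key
  first <- first[keep_keys, , drop = FALSE]
  entries <- data.frame(
    key = keep_keys,
    chrom = first$chrom, pos = first$pos, ref = first$ref, alt = first$alt,
    median_vaf = unname(med_vaf[keep_keys]),
    support = as.integer(unname(support[keep_keys])),
    n = rep.int(n, length(keep_keys)),
    zygosity = classify_zygosity(unname(med_vaf[keep_keys])),
    in_ctr = if (is.null(ctr)) rep(NA, length(keep_keys)) else
      region_contains(ctr, first$chrom, first$pos),
    stringsAsFactors = FALSE
  )
  entries <- entries[order(entries$chrom, entries$pos, entries$ref, entries$alt), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(panel = panel, n_reference_samples = n, fraction = fraction,
                 entries = entries), class = "KnownVariantSet")
}

#' @export
print.KnownVariantSet <- function(x, ...) {
  cat(sprintf("KnownVariantSet%s: %d variants from %d reference samples (support > %g%%)\n",
              if (nzchar(x$panel)) paste0(" '", x$panel, "'") else "",
              nrow(x$entries), x$n_reference_samples, 100 * x$fraction))
  if (nrow(x$entries)) {
    print(table(factor(x$entries$zygosity, levels = zygosity_bins)), ...)
  }
  invisible(x)
}

#' Tabulate known variants by zygosity bin and CTR membership
#'
#' @param known a `KnownVariantSet` whose entries carry `in_ctr` flags.
#' @return Data frame with one row per zygosity bin and count/percentage
#'   columns for inside and outside the CTR. Percentages sum to 100 within
#'   each region (0 for an empty region, no division error).
#' @export
summarize_known_by_region <- function(known) {
  stopifnot(inherits(known, "KnownVariantSet"))
  e <- known$entries
  if (nrow(e) == 0) stop("known set is empty")
  if (all(is.na(e$in_ctr))) stop("known set has no CTR membership flags")
  zyg <- factor(e$zygosity, levels = zygosity_bins)
  tab_in <- table(zyg[e$in_ctr])
  tab_out <- table(zyg[!e$in_ctr])
  pct <- function(x) if (sum(x) == 0) rep(0, length(x)) else 100 * x / sum(x)
  data.frame(
    zygosity = zygosity_bins,
    in_ctr_count = as.integer(tab_in),
    in_ctr_pct = as.numeric(pct(as.integer(tab_in))),
    out_ctr_count = as.integer(tab_out),
    out_ctr_pct = as.numeric(pct(as.integer(tab_out))),
    stringsAsFactors = FALSE
  )
}

#' Read/write a known-variant set as TSV
#'
#' @param known a `KnownVariantSet`.
#' @param path file path.
#' @return `write_known_set` returns `path` invisibly; `read_known_set`
#'   returns a `KnownVariantSet`.
#' @export
write_known_set <- function(known, path) {
  stopifnot(inherits(known, "KnownVariantSet"))
  utils::write.table(known$entries, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_known_set
#' @param panel,fraction metadata restored onto the read object.
#' @export
read_known_set <- function(path, panel = "", fraction = 0.75) {
  entries <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = c(chrom = "character",
                                              ref = "character",
                                              alt = "character"))
  structure(list(panel = panel,
                 n_reference_samples = if (nrow(entries)) entries$n[1] else 0L,
                 fraction = fraction, entries = entries),
            class = "KnownVariantSet")
}

#' Write a known set as a sites-only VCF
#'
#' @param known a `KnownVariantSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_known_set_vcf <- function(known, path) {
  stopifnot(inherits(known, "KnownVariantSet"))
  e <- known$entries
  header <- c("##fileformat=VCFv4.2",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  body <- if (nrow(e) == 0) character(0) else {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMEDIAN_VAF=%s;SUPPORT=%d",
            e$chrom, as.integer(e$pos), e$ref, e$alt,
            format(e$median_vaf, trim = TRUE, digits = 6), e$support)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
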