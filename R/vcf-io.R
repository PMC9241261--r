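#' Panel configuration
#'
#' Bundles everything panel-specific the cleaning and FP stages need: the
#' targeted region, the low-complexity exclusion, the vendor-recommended
#' VAF threshold, and an optional blocklist of variant keys. The assessable
#' region size (`region_size_bases`) is the targeted region minus the
#' low-complexity regions and is the denominator of whole-panel FPR.
#'
#' @param name panel identifier.
#' @param target_region `RegionSet` of targeted bases.
#' @param low_complexity `RegionSet` removed from the target before any
#'   analysis; `NULL` for none.
#' @param default_vaf_threshold vendor-recommended VAF threshold in (0, 1),
#'   applied inclusively (`vaf >= threshold`).
#' @param blocklist character vector of normalized variant keys
#'   (`chrom:pos:ref:alt`) to drop during cleaning.
#' @return A `PanelConfig` object.
#' @export
panel_config <- function(name, target_region, low_complexity = NULL,
                         default_vaf_threshold, blocklist = character()) {
  stopifnot(is_region_set(target_region))
  if (!is.null(low_complexity)) stopifnot(is_region_set(low_complexity))
  if (!(default_vaf_threshold > 0 && default_vaf_threshold < 1)) {
    stop("default_vaf_threshold must be in (0, 1)")
  }
  effective <- if (is.null(low_complexity)) {
    target_region
  } else {
    region_subtract(target_region, low_complexity)
  }
  structure(list(
    name = name,
    target_region = target_region,
    low_complexity = low_complexity,
    effective_region = effective,
    default_vaf_threshold = default_vaf_threshold,
    blocklist = as.character(blocklist),
    region_size_bases = total_bases(effective)
  ), class = "PanelConfig")
}

#' @export
print.PanelConfig <- function(x, ...) {
  cat(sprintf("PanelConfig '%s': %s assessable bases, VAF threshold %g, %d blocklisted key(s)\n",
              x$name, format(x$region_size_bases, big.mark = ","),
              x$default_vaf_threshold, length(x$blocklist)))
  invisible(x)
}

# parse one FORMAT/sample pair of a VCF line into a named list
parse_format <- function(format, value) {
  stats::setNames(strsplit(value, ":", fixed = TRUE)[[1]],
                  strsplit(format, ":", fixed = TRUE)[[1]])
}

nth_comma_field <- function(x, n) {
  vapply(seq_along(x), function(i) {
    parts <- strsplit(x[i], ",", fixed = TRUE)[[1]]
    if (n[i] <= length(parts)) parts[n[i]] else NA_character_
  }, character(1))
}

info_tag <- function(info, tag) {
  m <- regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]*"), info))
  out <- rep(NA_character_, length(info))
  hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", tag, "="), info))) > 0
  out[hit] <- sub(paste0("^.*", tag, "="), "", m)
  out
}

#' Read a per-sample VCF into a variant frame
#'
#' Reads CHROM, POS, REF, ALT, FILTER and the allele-frequency/depth fields
#' from a VCF 4.x file via \pkg{vcfR}. Multi-allelic lines are split into one
#' record per alternate allele before any downstream normalization. VAF is
#' taken from the `af_tag` FORMAT (then INFO) field; if absent it is derived
#' as `alt_depth / total_depth`, and an error is raised if neither source is
#' available, since every downstream stage requires a VAF.
#'
#' @param path VCF file path.
#' @param sample_id sample identifier; defaults to the VCF sample column
#'   name, or the file name for site-only files.
#' @param af_tag,dp_tag,ad_tag FORMAT/INFO tag names for allele fraction,
#'   total depth and allelic depths (AD is read as the conventional
#'   comma-separated `ref,alt1,...` list).
#' @param pass_only keep only records whose FILTER is `PASS` or `.`
#'   (default); set `FALSE` to ingest everything.
#' @param chrom_normalize as in [parse_bed].
#' @return A variant data frame (see [variant_frame]). Records with
#'   non-ACGT alleles (symbolic, breakend, `*`) are dropped with a warning.
#' @export
read_sample_vcf <- function(path, sample_id = NULL, af_tag = "AF",
                            dp_tag = "DP", ad_tag = "AD", pass_only = TRUE,
                            chrom_normalize = c("none", "strip", "add")) {
  chrom_normalize <- match.arg(chrom_normalize)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  has_gt <- ncol(v@gt) >= 2
  if (is.null(sample_id)) {
    sample_id <- if (has_gt) colnames(v@gt)[2] else sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  if (nrow(fix) == 0) {
    return(variant_frame(sample_id = character(0)))
  }
  if (pass_only) {
    keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  } else {
    keep <- rep(TRUE, nrow(fix))
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- if (has_gt) v@gt[keep, , drop = FALSE] else NULL
  if (nrow(fix) == 0) return(variant_frame(sample_id = character(0)))

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    fmt <- if (!is.null(gt)) parse_format(gt[i, 1], gt[i, 2]) else character(0)
    info <- fix$INFO[i]
    af_raw <- if (af_tag %in% names(fmt)) fmt[[af_tag]] else info_tag(info, af_tag)
    dp_raw <- if (dp_tag %in% names(fmt)) fmt[[dp_tag]] else info_tag(info, dp_tag)
    ad_raw <- if (ad_tag %in% names(fmt)) fmt[[ad_tag]] else info_tag(info, ad_tag)
    dp <- suppressWarnings(as.numeric(dp_raw))
    lapply(seq_along(alts), function(j) {
      af <- suppressWarnings(as.numeric(nth_comma_field(af_raw, j)))
      ad <- suppressWarnings(as.numeric(nth_comma_field(ad_raw, j + 1)))
      if (is.na(af)) {
        if (!is.na(ad) && !is.na(dp) && dp > 0) {
          af <- ad / dp
        } else {
          stop("no VAF available (no ", af_tag, " tag and no usable ",
               ad_tag, "/", dp_tag, ") at ", fix$CHROM[i], ":", fix$POS[i])
        }
      }
      list(chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
           ref = fix$REF[i], alt = alts[j], vaf = min(max(af, 0), 1),
           dp = dp, ad = ad)
    })
  })
  rows <- unlist(rows, recursive = FALSE)
  df <- data.frame(
    chrom = normalize_chrom(vapply(rows, `[[`, "", "chrom"), chrom_normalize),
    pos = vapply(rows, `[[`, 0, "pos"),
    ref = toupper(vapply(rows, `[[`, "", "ref")),
    alt = toupper(vapply(rows, `[[`, "", "alt")),
    vaf = vapply(rows, `[[`, 0, "vaf"),
    total_depth = vapply(rows, `[[`, 0, "dp"),
    alt_depth = vapply(rows, `[[`, 0, "ad"),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  ok <- grepl("^[ACGT]+$", df$ref) & grepl("^[ACGT]+$", df$alt)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with non-ACGT alleles dropped")
    df <- df[ok, , drop = FALSE]
  }
  rownames(df) <- NULL
  validate_variants(df)
  df
}

#' Write a variant frame as a minimal VCF 4.2 file
#'
#' One sample column carrying `AF:DP:AD` FORMAT fields (AD as the
#' conventional `ref,alt` pair). Records are sorted by (chrom, pos).
#'
#' @param df variant data frame.
#' @param path output path.
#' @param sample_id sample column name; defaults to the frame's `sample_id`.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(df, path, sample_id = NULL) {
  validate_variants(df)
  if (is.null(sample_id)) {
    sample_id <- if (nrow(df) > 0 && !is.na(df$sample_id[1])) df$sample_id[1] else "SAMPLE"
  }
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Variant allele fraction">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- if (nrow(df) == 0) character(0) else {
    dp <- ifelse(is.na(df$total_depth), ".", format(df$total_depth, trim = TRUE, scientific = FALSE))
    ad <- ifelse(is.na(df$alt_depth) | is.na(df$total_depth), ".",
                 paste0(format(df$total_depth - df$alt_depth, trim = TRUE, scientific = FALSE),
                        ",", format(df$alt_depth, trim = TRUE, scientific = FALSE)))
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAF:DP:AD\t%s:%s:%s",
            df$chrom, as.integer(df$pos), df$ref, df$alt,
            format(df$vaf, trim = TRUE, digits = 6, scientific = FALSE), dp, ad)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write variant frames as TSV
#'
#' Plain tab-separated interchange format with columns
#' `sample_id, chrom, pos, ref, alt, vaf, total_depth, alt_depth`.
#'
#' @param df variant data frame.
#' @param path file path.
#' @return `write_variants_tsv` returns `path` invisibly;
#'   `read_variants_tsv` returns a variant data frame.
#' @export
write_variants_tsv <- function(df, path) {
  validate_variants(df)
  utils::write.table(df[, variant_columns], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character", ref = "character",
                                         alt = "character", sample_id = "character"))
  validate_variants(df)
  df
}

#' Load a germline-database variant list
#'
#' Accepts either a (sites-only) VCF or a headerless/headered 4-column TSV
#' of `chrom, pos, ref, alt`, and returns the set of normalized variant
#' keys used for contamination confirmation.
#'
#' @param path file path (`.vcf` or `.tsv`).
#' @return Character vector of variant keys `chrom:pos:ref:alt`.
#' @export
read_germline_db <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0) return(character(0))
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    rep_i <- rep(seq_len(nrow(fix)), lengths(alts))
    paste(fix$CHROM[rep_i], fix$POS[rep_i], fix$REF[rep_i],
          unlist(alts), sep = ":")
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("chrom", "pos", "ref", "alt") %in% names(df))) {
      df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "pos", "ref", "alt"))
    }
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  }
}
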