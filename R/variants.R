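#' Variant records
#'
#' Variant calls flow through the pipeline as plain data frames with one row
#' per atomic (biallelic, normalized) call and columns:
#' \describe{
#'   \item{chrom}{chromosome name}
#'   \item{pos}{1-based position of the first reference base}
#'   \item{ref, alt}{reference / alternate allele (ACGT, non-empty)}
#'   \item{vaf}{variant allele fraction in \[0, 1\]}
#'   \item{total_depth}{reads covering the locus}
#'   \item{alt_depth}{reads supporting the alternate allele}
#'   \item{sample_id}{sample identifier}
#' }
#' Variant identity everywhere in the package is the key
#' `chrom:pos:ref:alt` computed on the normalized representation, so that
#' matching against known sets is representation-invariant.
#'
#' @param chrom,pos,ref,alt,vaf,total_depth,alt_depth,sample_id column values
#'   (recycled to a common length by `data.frame`).
#' @return A validated variant data frame.
#' @export
variant_frame <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          vaf = numeric(), total_depth = NA_real_,
                          alt_depth = NA_real_, sample_id = NA_character_) {
  if (length(chrom) == 0) {
    df <- data.frame(chrom = character(), pos = numeric(), ref = character(),
                     alt = character(), vaf = numeric(),
                     total_depth = numeric(), alt_depth = numeric(),
                     sample_id = character(), stringsAsFactors = FALSE)
    return(df)
  }
  df <- data.frame(
    chrom = as.character(chrom), pos = as.numeric(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    vaf = as.numeric(vaf), total_depth = as.numeric(total_depth),
    alt_depth = as.numeric(alt_depth), sample_id = as.character(sample_id),
    stringsAsFactors = FALSE
  )
  validate_variants(df)
  df
}

variant_columns <- c("chrom", "pos", "ref", "alt", "vaf",
                     "total_depth", "alt_depth", "sample_id")

validate_variants <- function(df) {
  missing_cols <- setdiff(variant_columns, names(df))
  if (length(missing_cols)) {
    stop("variant frame missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  if (any(!grepl("^[ACGT]+$", df$ref)) || any(!grepl("^[ACGT]+$", df$alt))) {
    stop("alleles must be non-empty ACGT strings")
  }
  if (any(df$vaf < 0 | df$vaf > 1, na.rm = TRUE)) stop("vaf outside [0, 1]")
  both <- !is.na(df$alt_depth) & !is.na(df$total_depth)
  if (any(df$alt_depth[both] > df$total_depth[both])) {
    stop("alt_depth exceeds total_depth")
  }
  invisible(df)
}

#' Variant identity key
#'
#' @param df variant data frame (or anything with chrom/pos/ref/alt columns).
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
variant_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Is a variant an indel?
#'
#' @param ref,alt allele strings.
#' @return Logical: `TRUE` where allele lengths differ.
#' @export
is_indel <- function(ref, alt) nchar(ref) != nchar(alt)

# ---- reference sequence accessors -------------------------------------------

#' Reference sequence accessors
#'
#' Normalization needs random access to the reference. An accessor is a
#' function `f(chrom, start, end)` returning the reference bases on `chrom`
#' from `start` to `end` (1-based, inclusive) as an uppercase string.
#'
#' `ref_accessor_from_seqs` builds one from a named character vector of
#' chromosome sequences; `ref_accessor_from_fasta` reads a FASTA file (via
#' Biostrings) into memory first.
#'
#' @param seqs named character vector, one element per chromosome.
#' @return A function `(chrom, start, end) -> character`.
#' @export
ref_accessor_from_seqs <- function(seqs) {
  seqs <- toupper(seqs)
  function(chrom, start, end) {
    s <- seqs[[chrom]]
    if (is.null(s)) stop("no reference sequence for chromosome ", chrom)
    if (start < 1 || end > nchar(s)) {
      stop("reference access out of bounds on ", chrom)
    }
    substr(s, start, end)
  }
}

#' @rdname ref_accessor_from_seqs
#' @param path FASTA file path.
#' @export
ref_accessor_from_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ref_accessor_from_seqs(seqs)
}

# ---- normalization ----------------------------------------------------------

# normalize one (pos, ref, alt) against a reference accessor: trim shared
# suffix/prefix, and left-align indels keeping the standard single anchor
# base. Returns list(pos, ref, alt).
normalize_one <- function(chrom, pos, ref, alt, reference) {
  observed <- reference(chrom, pos, pos + nchar(ref) - 1)
  if (observed != ref) {
    stop(sprintf("ref allele '%s' at %s:%d disagrees with reference '%s'",
                 ref, chrom, pos, observed))
  }
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # trim shared suffix
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # trim shared prefix
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  if (length(r) != length(a)) {
    # indel: left-align, then reduce to anchored minimal form
    repeat {
      if (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)]) {
        r <- r[-length(r)]
        a <- a[-length(a)]
      } else if (length(r) == 0 || length(a) == 0) {
        if (pos == 1) {
          # no base to the left: anchor on the base following the event
          b <- reference(chrom, pos + length(r), pos + length(r))
          r <- c(r, b)
          a <- c(a, b)
          break
        }
        pos <- pos - 1
        b <- reference(chrom, pos, pos)
        r <- c(b, r)
        a <- c(b, a)
      } else {
        break
      }
    }
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos <- pos + 1
    }
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Left-align and trim variants
#'
#' Produces the unique minimal representation of each variant: shared
#' prefix/suffix bases are trimmed, and indels are shifted maximally left
#' through repeated sequence (keeping the standard single anchor base before
#' the inserted/deleted bases). SNVs and MNVs pass through trimmed only. The
#' operation is idempotent and preserves the haplotype change the variant
#' describes.
#'
#' @param df variant data frame.
#' @param reference a reference accessor (see [ref_accessor_from_seqs]).
#' @return The data frame with `pos`, `ref`, `alt` normalized.
#' @export
left_align_and_trim <- function(df, reference) {
  validate_variants(df)
  if (nrow(df) == 0) return(df)
  for (i in seq_len(nrow(df))) {
    n <- normalize_one(df$chrom[i], df$pos[i], df$ref[i], df$alt[i], reference)
    df$pos[i] <- n$pos
    df$ref[i] <- n$ref
    df$alt[i] <- n$alt
  }
  df
}

#' Decompose multi-nucleotide variants into SNVs
#'
#' A trimmed MNV (`|ref| == |alt| > 1`) becomes one SNV per differing base,
#' each inheriting the parent's VAF and depths; SNVs and indels are returned
#' unchanged. The set of per-base differences between the ref and alt
#' haplotypes is conserved.
#'
#' @param df variant data frame (trimmed).
#' @return Variant data frame of atomic records.
#' @export
decompose_complex <- function(df) {
  validate_variants(df)
  if (nrow(df) == 0) return(df)
  mnv <- nchar(df$ref) == nchar(df$alt) & nchar(df$ref) > 1
  if (!any(mnv)) return(df)
  pieces <- lapply(which(mnv), function(i) {
    r <- strsplit(df$ref[i], "")[[1]]
    a <- strsplit(df$alt[i], "")[[1]]
    d <- which(r != a)
    out <- df[rep(i, length(d)), , drop = FALSE]
    out$pos <- df$pos[i] + d - 1
    out$ref <- r[d]
    out$alt <- a[d]
    out
  })
  out <- rbind(df[!mnv, , drop = FALSE], do.call(rbind, pieces))
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize a variant frame end to end
#'
#' Convenience wrapper: [left_align_and_trim] followed by
#' [decompose_complex].
#'
#' @inheritParams left_align_and_trim
#' @return Atomic, normalized variant data frame.
#' @export
normalize_variants <- function(df, reference) {
  decompose_complex(left_align_and_trim(df, reference))
}
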