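#' Genomic region sets
#'
#' A `RegionSet` is a canonical collection of genomic intervals: sorted by
#' (chromosome, start), non-overlapping, with book-ended (adjacent) intervals
#' merged. It is the container for panel target regions, low-complexity
#' regions, and the consensus high-confidence targeted region (CTR).
#' Coordinates follow BED conventions: 0-based, half-open `[start, end)`.
#' Strand is ignored throughout, since variant positions are strandless.
#'
#' Internally a `RegionSet` wraps a [GenomicRanges::GRanges] (1-based closed);
#' the conversion happens once at construction and once on export.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive starts.
#' @param end integer vector, 0-based exclusive ends; `start < end` required.
#' @param label free-text label carried along for reporting.
#' @return A `RegionSet` object.
#' @examples
#' rs <- region_set("chr1", c(10, 15), c(20, 30))
#' total_bases(rs) # 20: the two overlapping intervals merge to [10, 30)
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), label = "") {
  if (length(start) != length(end)) {
    stop("start and end must have equal length")
  }
  if (length(chrom) == 1 && length(start) > 1) {
    chrom <- rep(chrom, length(start))
  }
  if (length(chrom) != length(start)) {
    stop("chrom must match the length of start/end (or be a scalar)")
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) stop("non-integer coordinates")
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("start must be < end for every interval")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
  new_region_set(gr, label)
}

# wrap a GRanges: sort + reduce gives the canonical form (merges overlaps
# and book-ended neighbours). A plain per-chromosome interval index (0-based
# half-open, sorted) is kept alongside for fast membership lookups.
new_region_set <- function(gr, label = "") {
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr), ignore.strand = TRUE)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  index <- lapply(split(seq_along(chrom), chrom), function(i) {
    list(start = start0[i], end = end0[i])
  })
  structure(list(gr = gr, index = index,
                 tb = sum(as.numeric(end0 - start0)), label = label),
            class = "RegionSet")
}

is_region_set <- function(x) inherits(x, "RegionSet")

# put two GRanges on a shared seqlevel universe so set operations are quiet
# even when the sets cover different chromosomes
harmonize_seqlevels <- function(a, b) {
  sl <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- sl
  GenomeInfoDb::seqlevels(b) <- sl
  list(a = a, b = b)
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf(
    "RegionSet%s: %d interval(s), %s bases on %d chromosome(s)\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    length(x$gr), format(total_bases(x), big.mark = ","),
    length(unique(as.character(GenomicRanges::seqnames(x$gr))))
  ))
  invisible(x)
}

#' Total number of bases covered by a RegionSet
#'
#' @param rs a `RegionSet`.
#' @return Numeric scalar, the sum of interval widths of the canonical set.
#' @export
total_bases <- function(rs) {
  stopifnot(is_region_set(rs))
  rs$tb
}

#' Convert a RegionSet to a BED-style data frame
#'
#' @param x a `RegionSet`.
#' @param ... ignored.
#' @return data.frame with `chrom`, `start` (0-based), `end` (exclusive).
#' @export
as.data.frame.RegionSet <- function(x, ...) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(x$gr)),
    start = GenomicRanges::start(x$gr) - 1,
    end = GenomicRanges::end(x$gr),
    stringsAsFactors = FALSE
  )
}

normalize_chrom <- function(chrom, chrom_normalize = c("none", "strip", "add")) {
  chrom_normalize <- match.arg(chrom_normalize)
  switch(chrom_normalize,
    none = chrom,
    strip = sub("^chr", "", chrom),
    add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
}

#' Parse a BED3+ file into a RegionSet
#'
#' Reads a tab-separated BED file (0-based half-open coordinates). Lines
#' starting with `track`, `browser` or `#` and blank lines are skipped;
#' columns beyond the third are ignored. Malformed lines (fewer than three
#' columns, non-integer coordinates, `start >= end`) raise an error naming
#' the offending line number.
#'
#' @param path path to the BED file.
#' @param label label for the resulting set; defaults to the file name.
#' @param chrom_normalize `"none"` (default) leaves chromosome names exactly
#'   as written; `"strip"` removes a leading `"chr"`, `"add"` prepends one.
#'   Names are otherwise compared as exact strings — the parser never remaps
#'   between genome builds.
#' @return A canonical `RegionSet`.
#' @export
parse_bed <- function(path, label = basename(path),
                      chrom_normalize = c("none", "strip", "add")) {
  chrom_normalize <- match.arg(chrom_normalize)
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(region_set(label = label))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED parse error at line ", idx[which(nf < 3)[1]],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad)) {
    stop("BED parse error at line ", idx[which(bad)[1]],
         ": non-integer coordinates or start >= end")
  }
  region_set(normalize_chrom(chrom, chrom_normalize), start, end, label = label)
}

#' Write a RegionSet as BED3
#'
#' @param rs a `RegionSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path) {
  df <- as.data.frame(rs)
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), path)
  invisible(path)
}

#' Intersect two RegionSets
#'
#' @param a,b canonical `RegionSet`s.
#' @return `RegionSet` containing exactly the bases present in both.
#' @export
region_intersect <- function(a, b) {
  stopifnot(is_region_set(a), is_region_set(b))
  h <- harmonize_seqlevels(a$gr, b$gr)
  new_region_set(GenomicRanges::intersect(h$a, h$b, ignore.strand = TRUE),
                 label = a$label)
}

#' Subtract one RegionSet from another
#'
#' @param a,b canonical `RegionSet`s.
#' @return `RegionSet` of the bases in `a` and not in `b`.
#' @export
region_subtract <- function(a, b) {
  stopifnot(is_region_set(a), is_region_set(b))
  h <- harmonize_seqlevels(a$gr, b$gr)
  new_region_set(GenomicRanges::setdiff(h$a, h$b, ignore.strand = TRUE),
                 label = a$label)
}

#' Test membership of variant positions in a RegionSet
#'
#' Positions are 1-based (VCF convention); the 0-based/1-based conversion
#' between BED and VCF happens only here. Lookup is a binary search
#' (`findInterval`) over the canonical sorted intervals, i.e. logarithmic
#' in the interval count.
#'
#' @param rs a `RegionSet`.
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos 1-based position(s).
#' @return Logical vector: `TRUE` where the position lies inside the set.
#' @export
region_contains <- function(rs, chrom, pos) {
  stopifnot(is_region_set(rs))
  if (length(pos) == 0) return(logical(0))
  chrom <- as.character(chrom)
  if (length(chrom) == 1 && length(pos) > 1) chrom <- rep(chrom, length(pos))
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    iv <- rs$index[[ch]]
    sel <- chrom == ch
    if (is.null(iv)) next
    p0 <- pos[sel] - 1
    j <- findInterval(p0, iv$start)
    out[sel] <- j >= 1 & p0 < iv$end[pmax(j, 1)]
  }
  out
}

#' Build the consensus high-confidence targeted region (CTR)
#'
#' Folds the component region sets (e.g. exonic coding regions, a
#' high-confidence benchmark region, targeted regions of exome panels) by
#' intersection, then removes the low-complexity regions. Which
#' low-complexity definition to use is the caller's choice — any BED is
#' accepted and none is hard-coded.
#'
#' @param components non-empty list of `RegionSet`s to intersect.
#' @param low_complexity `RegionSet` to subtract afterwards; `NULL` for none.
#' @return Canonical `RegionSet`. If the component intersection is empty a
#'   warning is emitted and an empty set returned.
#' @export
build_ctr <- function(components, low_complexity = NULL) {
  if (!is.list(components) || length(components) == 0) {
    stop("components must be a non-empty list of RegionSets")
  }
  stopifnot(all(vapply(components, is_region_set, logical(1))))
  out <- Reduce(region_intersect, components)
  if (total_bases(out) == 0) {
    warning("component intersection is empty")
  }
  if (!is.null(low_complexity)) out <- region_subtract(out, low_complexity)
  out$label <- "CTR"
  out
}
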