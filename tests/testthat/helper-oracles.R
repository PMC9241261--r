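# Independent brute-force oracles used to cross-check the implementation.
# They deliberately share no code with the package internals.

# ---- region algebra: boolean-array oracle on a toy genome -------------------

# represent a region set as a per-chromosome logical base mask (0-based index
# i maps to mask position i + 1)
mask_from_df <- function(df, chroms, genome_len) {
  masks <- lapply(chroms, function(ch) rep(FALSE, genome_len))
  names(masks) <- chroms
  for (i in seq_len(nrow(df))) {
    masks[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  masks
}

mask_from_region_set <- function(rs, chroms, genome_len) {
  mask_from_df(as.data.frame(rs), chroms, genome_len)
}

mask_total_bases <- function(masks) sum(vapply(masks, sum, numeric(1)))

mask_op <- function(a, b, op) {
  out <- a
  for (ch in names(a)) {
    out[[ch]] <- switch(op,
      intersect = a[[ch]] & b[[ch]],
      subtract = a[[ch]] & !b[[ch]]
    )
  }
  out
}

masks_equal <- function(a, b) all(mapply(identical, a, b))

# random RegionSet on a toy genome, returned with its raw interval df
random_region_df <- function(chroms, genome_len, max_intervals = 8) {
  n <- sample.int(max_intervals, 1)
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(genome_len - 1, n, replace = TRUE) - 1
  width <- sample.int(50, n, replace = TRUE)
  end <- pmin(start + width, genome_len)
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

# ---- known set: brute-force counting oracle ---------------------------------

oracle_known_keys <- function(sample_key_lists, fraction) {
  all_keys <- unique(unlist(sample_key_lists))
  n <- length(sample_key_lists)
  counts <- vapply(all_keys, function(k) {
    sum(vapply(sample_key_lists, function(ks) k %in% ks, logical(1)))
  }, numeric(1))
  sort(all_keys[counts > fraction * n])
}

# ---- statistics: textbook-formula oracles -----------------------------------

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p_two = 2 * pt(-abs(t), df),
       p_greater = pt(t, df, lower.tail = FALSE))
}

oracle_yates <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  adj <- pmax(abs(m - E) - 0.5, 0)
  chi2 <- sum(adj^2 / E)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# ---- indel normalization: exhaustive-shift oracle ---------------------------

# apply a variant to a reference string, returning the alternate haplotype
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, pos - 1), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# enumerate every equivalent representation (p, ref', alt') of a variant on a
# short reference by exhaustive shifting, and return the leftmost among the
# minimal-length ones. For a given start p and ref length rl, the alt allele
# is fully determined by requiring the alternate haplotype to match:
#   target = prefix(seq, p-1) + alt' + suffix(seq, from p+rl)
oracle_leftmost <- function(seq, pos, ref, alt) {
  target <- apply_variant(seq, pos, ref, alt)
  n <- nchar(seq)
  best <- NULL
  for (p in seq_len(n)) {
    if (substr(target, 1, p - 1) != substr(seq, 1, p - 1)) next
    for (rl in 1:(n - p + 1)) {
      r <- substr(seq, p, p + rl - 1)
      suffix_len <- n - (p + rl - 1)
      al <- nchar(target) - (p - 1) - suffix_len
      if (al < 1) next
      a <- substr(target, p, p - 1 + al)
      if (r == a) next
      if (substr(target, p + al, nchar(target)) !=
            substr(seq, p + rl, n)) next
      size <- rl + al
      if (is.null(best) || size < best$size ||
          (size == best$size && p < best$pos)) {
        best <- list(pos = p, ref = r, alt = a, size = size)
      }
    }
  }
  best[c("pos", "ref", "alt")]
}

# ---- shared fixtures --------------------------------------------------------

tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed, panel_size_bases = 2e5, n_het = 60, n_hom = 40,
               n_panels = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# normalized, cleaned view of a simulated sample (origins dropped)
sim_clean <- function(s, truth) {
  clean_sample(s[, setdiff(names(s), "origin")], truth$panel_cfg)
}
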