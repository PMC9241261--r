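test_that("region sets canonicalize: overlapping and book-ended intervals merge", {
  rs <- region_set("chr1", c(10, 15), c(20, 30))
  df <- as.data.frame(rs)
  expect_equal(nrow(df), 1)
  expect_equal(df$start, 10)
  expect_equal(df$end, 30)
  expect_equal(total_bases(rs), 20)

  # book-ended intervals are one base set
  rs2 <- region_set("chr1", c(0, 10), c(10, 20))
  expect_equal(nrow(as.data.frame(rs2)), 1)
  expect_equal(total_bases(rs2), 20)

  # canonicalization is idempotent
  rs3 <- do.call(region_set, c(as.data.frame(rs2), list(label = "again")))
  expect_equal(as.data.frame(rs3), as.data.frame(rs2))
})

test_that("BED parsing handles comments, empty files, and malformed lines", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=test", "# comment",
               "chr1\t10\t20\tfeature", "chr1\t15\t30", "chr2\t0\t5"), p)
  rs <- parse_bed(p)
  expect_equal(total_bases(rs), 25)
  expect_equal(nrow(as.data.frame(rs)), 2)

  writeLines(character(0), p)
  expect_equal(total_bases(parse_bed(p)), 0)

  writeLines("chr1\t20\t10", p)
  expect_error(parse_bed(p), "line 1")
  writeLines(c("chr1\t0\t10", "chr1\tx\t10"), p)
  expect_error(parse_bed(p), "line 2")

  # round trip through write_bed
  writeLines(c("chr1\t10\t20", "chr2\t5\t9"), p)
  rs <- parse_bed(p)
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(rs, p2)
  expect_equal(as.data.frame(parse_bed(p2)), as.data.frame(rs))

  # chr-prefix normalization is opt-in
  writeLines("1\t0\t10", p)
  expect_equal(as.data.frame(parse_bed(p, chrom_normalize = "add"))$chrom, "chr1")
  expect_equal(as.data.frame(parse_bed(p))$chrom, "1")
})

test_that("intersect and subtract match hand-worked examples", {
  a <- region_set("chr1", 0, 100)
  b <- region_set("chr1", 50, 150)
  expect_equal(as.data.frame(region_intersect(a, b)),
               data.frame(chrom = "chr1", start = 50, end = 100))
  expect_equal(as.data.frame(region_intersect(a, a)), as.data.frame(a))

  d <- region_subtract(a, region_set("chr1", 40, 60))
  expect_equal(as.data.frame(d),
               data.frame(chrom = "chr1", start = c(0, 60), end = c(40, 100)))
  expect_equal(as.data.frame(region_subtract(a, region_set())), as.data.frame(a))
})

test_that("contains respects 1-based positions and end-exclusive bounds", {
  rs <- region_set("chr1", 10, 20)
  expect_true(region_contains(rs, "chr1", 11))  # 0-based 10 is inside
  expect_true(region_contains(rs, "chr1", 20))  # 0-based 19, last base
  expect_false(region_contains(rs, "chr1", 21)) # end-exclusive
  expect_false(region_contains(rs, "chr1", 10)) # 0-based 9, before start
  expect_false(region_contains(rs, "chr2", 11)) # wrong chromosome
  expect_equal(region_contains(rs, "chr1", integer(0)), logical(0))
})

test_that("build_ctr folds intersections then removes low-complexity", {
  a <- region_set("chr1", 0, 100)
  expect_equal(as.data.frame(build_ctr(list(a))), as.data.frame(a))
  expect_error(build_ctr(list()), "non-empty")
  expect_warning(
    out <- build_ctr(list(region_set("chr1", 0, 10), region_set("chr1", 50, 60))),
    "empty"
  )
  expect_equal(total_bases(out), 0)
})

test_that("region algebra agrees base-by-base with a boolean-array oracle", {
  chroms <- c("c1", "c2")
  glen <- 1000
  set.seed(42)
  for (i in 1:60) {
    da <- random_region_df(chroms, glen)
    db <- random_region_df(chroms, glen)
    a <- do.call(region_set, da)
    b <- do.call(region_set, db)
    ma <- mask_from_df(da, chroms, glen)
    mb <- mask_from_df(db, chroms, glen)

    expect_equal(total_bases(a), mask_total_bases(ma))
    expect_true(masks_equal(mask_from_region_set(region_intersect(a, b), chroms, glen),
                            mask_op(ma, mb, "intersect")))
    expect_true(masks_equal(mask_from_region_set(region_subtract(a, b), chroms, glen),
                            mask_op(ma, mb, "subtract")))
    # algebraic identities
    expect_lte(total_bases(region_intersect(a, b)),
               min(total_bases(a), total_bases(b)))
    expect_equal(total_bases(region_subtract(a, b)),
                 total_bases(a) - total_bases(region_intersect(a, b)))
  }
})

test_that("contains matches a linear-scan oracle on random queries", {
  chroms <- c("c1", "c2")
  glen <- 1000
  set.seed(7)
  da <- random_region_df(chroms, glen)
  rs <- do.call(region_set, da)
  qc <- sample(chroms, 1000, replace = TRUE)
  qp <- sample.int(glen, 1000, replace = TRUE)
  got <- region_contains(rs, qc, qp)
  want <- vapply(seq_along(qp), function(i) {
    any(da$chrom == qc[i] & da$start <= qp[i] - 1 & qp[i] - 1 < da$end)
  }, logical(1))
  expect_equal(got, want)
})

test_that("build_ctr matches a per-base AND-then-ANDNOT oracle", {
  chroms <- "c1"
  glen <- 2000
  set.seed(99)
  for (i in 1:20) {
    dfs <- lapply(1:3, function(j) random_region_df(chroms, glen, 12))
    dlc <- random_region_df(chroms, glen, 6)
    # random components may legitimately have an empty intersection (warns)
    got <- suppressWarnings(
      build_ctr(lapply(dfs, function(d) do.call(region_set, d)),
                do.call(region_set, dlc))
    )
    masks <- lapply(dfs, mask_from_df, chroms = chroms, genome_len = glen)
    want <- Reduce(function(x, y) mask_op(x, y, "intersect"), masks)
    want <- mask_op(want, mask_from_df(dlc, chroms, glen), "subtract")
    expect_true(masks_equal(mask_from_region_set(got, chroms, glen), want))
  }
})
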