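sorted_random_bed <- function(path, n = 500, chroms = c("chr1", "chr2"),
                              span = 2e5) {
  recs <- purrr::map_dfr(chroms, function(cn) {
    reg <- genomic_region(cn, 0, span)
    r <- random_records(n, reg, value_range = c(0, 60))
    r[order(r$start), ]
  })
  write_bed(recs, path)
  recs
}

test_that("the in-memory source answers region queries exactly", {
  dir <- write_sim_dir(n_samples = 2, seed = 21)
  src <- bedfile_source(dir)
  expect_equal(src_samples(src), c("sample01", "sample02"))

  # empty region result, and full-span result
  expect_equal(nrow(src_query(src, "sample01", "chr9:0-1000")), 0L)
  full <- src_query(src, "sample01", "chr17:1.1M-1.2M")
  expect_equal(nrow(full), 1000L)

  expect_error(src_query(src, "nope", "chr17:1.1M-1.2M"), "unknown sample")
})

test_that("in-memory queries equal a brute-force linear scan", {
  set.seed(22)
  path <- withr::local_tempfile(fileext = ".bed")
  recs <- sorted_random_bed(path, n = 1000)
  src <- bedfile_source(path)
  sample_id <- src_samples(src)[1]
  for (i in 1:100) {
    cn <- sample(c("chr1", "chr2", "chr3"), 1)
    a <- sort(sample(0:2e5, 2))
    if (a[1] == a[2]) a[2] <- a[2] + 1
    reg <- genomic_region(cn, a[1], a[2])
    expect_same_records(src_query(src, sample_id, reg),
                        linear_scan(recs, reg))
  }
})

test_that("indexing rejects unsorted input with the offending line", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t100\t200\t1", "chrA\t50\t80\t2"), path)
  expect_error(build_index(path), "line 2.*sort")

  # non-contiguous chromosome block
  path2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t0\t10\t1", "chrB\t0\t10\t1", "chrA\t20\t30\t1"), path2)
  expect_error(build_index(path2), "contiguous.*line 3")

  path3 <- withr::local_tempfile(fileext = ".bed")
  write_bed(tibble::tibble(chrom = "chrA", start = 0, end = 100, value = 1),
            path3)
  expect_error(build_index(path3, bin_size_bp = 1000), "power of two")
})

test_that("an empty BED yields a valid empty index; a single record maps bin 0", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), p)
  idx <- build_index(p)
  expect_length(idx$tables, 0L)
  expect_equal(nrow(indexed_query(p, "chrA:0-100", idx)), 0L)

  p2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrA\t0\t100\t3.5", p2)
  idx2 <- build_index(p2)
  expect_equal(idx2$tables$chrA, 0)
})

test_that("the sidecar index round-trips through its binary format", {
  path <- withr::local_tempfile(fileext = ".bed")
  set.seed(23)
  sorted_random_bed(path, n = 200)
  idx <- build_index(path, bin_size_bp = 4096L)
  back <- read_index(path)
  expect_equal(back, idx)
  # deterministic given identical input bytes
  f1 <- readBin(paste0(path, ".hbi"), "raw", file.size(paste0(path, ".hbi")))
  build_index(path, bin_size_bp = 4096L)
  f2 <- readBin(paste0(path, ".hbi"), "raw", file.size(paste0(path, ".hbi")))
  expect_identical(f1, f2)
})

test_that("indexed queries agree with linear scans on fuzzed files", {
  set.seed(24)
  for (rep in 1:4) {
    path <- withr::local_tempfile(fileext = ".bed")
    recs <- sorted_random_bed(path, n = sample(50:800, 1))
    idx <- build_index(path, bin_size_bp = sample(c(1024L, 16384L), 1))
    for (i in 1:25) {
      cn <- sample(c("chr1", "chr2", "chrZ"), 1)
      a <- sort(sample(0:250000, 2))
      if (a[1] == a[2]) a[2] <- a[2] + 1
      reg <- genomic_region(cn, a[1], a[2])
      expect_same_records(indexed_query(path, reg, idx),
                          linear_scan(recs, reg))
    }
    # region beyond the last record is empty
    expect_equal(nrow(indexed_query(path, "chr1:900000-950000", idx)), 0L)
    # whole-chromosome region returns the chromosome's records
    expect_same_records(indexed_query(path, "chr2:0-1000000", idx),
                        linear_scan(recs, genomic_region("chr2", 0, 1e6)))
  }
})

test_that("indexed queries scan a bounded slice, not the whole file", {
  # many records, query at the far end: the scan must not start at offset 0
  path <- withr::local_tempfile(fileext = ".bed")
  n <- 5000L
  recs <- tibble::tibble(chrom = "chrA", start = seq(0, by = 100, length.out = n),
                         end = seq(100, by = 100, length.out = n), value = 1)
  write_bed(recs, path)
  idx <- build_index(path, bin_size_bp = 16384L)
  q <- indexed_query(path, genomic_region("chrA", 400000, 401000), idx)
  expect_equal(nrow(q), 10L)
  # at most the records of the first overlapping bin plus the stop record
  expect_lt(attr(q, "n_scanned"), 16384 / 100 + 20)
})

test_that("a stale index is refused", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t0\t10\t1", "chrA\t10\t20\t2"), path)
  idx <- build_index(path)
  writeLines(c("chrA\t0\t10\t9", "chrA\t10\t20\t9"), path)
  expect_error(indexed_query(path, "chrA:0-20", idx), "stale")
})

test_that("gzipped files cannot be indexed", {
  gz <- withr::local_tempfile(fileext = ".bed.gz")
  write_bed(tibble::tibble(chrom = "chrA", start = 0, end = 5, value = 1), gz)
  expect_error(build_index(gz), "gzip")
})
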