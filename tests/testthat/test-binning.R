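# Pixel binning is checked against per_base_expand(), the brute-force
# per-base reference implementation of the same semantics.

oracle_bin <- function(records, ctx, aggregator, gap_policy = "missing") {
  per_base_bin(per_base_expand(records, ctx$region, aggregator), ctx,
               aggregator, gap_policy)
}

test_that("per-base expansion realizes the documented semantics", {
  reg <- genomic_region("chrA", 0, 5)
  one <- tibble::tibble(chrom = "chrA", start = 2, end = 4, value = 7)
  expect_equal(per_base_expand(one, reg), c(NA, NA, 7, 7, NA))

  two <- tibble::tibble(chrom = "chrA", start = c(0, 1), end = c(3, 5),
                        value = c(1, 3))
  expect_equal(per_base_expand(two, reg, "max"), c(1, 3, 3, 3, 3))
  expect_equal(per_base_expand(two, reg, "min"), c(1, 1, 1, 3, 3))
  expect_equal(per_base_expand(two, reg, "mean"), c(1, 2, 2, 3, 3))
  expect_equal(per_base_expand(two, reg, "sum"), c(1, 4, 4, 3, 3))

  big <- genomic_region("chrA", 0, 2e6)
  expect_error(per_base_expand(one, big), "1e6")
})

test_that("constant full-cover signal bins to the constant everywhere", {
  ctx <- chart_context(genomic_region("chrA", 0, 997), width_px = 64)
  rec <- tibble::tibble(chrom = "chrA", start = 0, end = 997, value = 5.5)
  for (agg in c("mean", "max", "min", "sum")) {
    expect_equal(bin_records(rec, ctx, agg)$value, rep(5.5, 64),
                 tolerance = 1e-12)
  }
})

test_that("two half-region records average to their midpoint", {
  ctx <- chart_context(genomic_region("chrA", 0, 10), width_px = 1)
  recs <- tibble::tibble(chrom = "chrA", start = c(0, 5), end = c(5, 10),
                         value = c(10, 20))
  expect_equal(bin_records(recs, ctx, "mean")$value, 15)
  expect_equal(bin_records(recs, ctx, "max")$value, 20)
  expect_equal(bin_records(recs, ctx, "sum")$value, 15)
})

test_that("gap policy controls uncovered columns", {
  ctx <- chart_context(genomic_region("chrA", 0, 100), width_px = 10)
  none <- tibble::tibble(chrom = character(), start = numeric(),
                         end = numeric(), value = numeric())
  expect_true(all(is.na(bin_records(none, ctx, gap_policy = "missing")$value)))
  expect_equal(bin_records(none, ctx, gap_policy = "zero")$value, rep(0, 10))

  partial <- tibble::tibble(chrom = "chrA", start = 0, end = 30, value = 2)
  v <- bin_records(partial, ctx, gap_policy = "missing")$value
  expect_equal(v, c(2, 2, 2, rep(NA, 7)))
})

test_that("records off-context are clipped or ignored", {
  ctx <- chart_context(genomic_region("chrA", 100, 200), width_px = 10)
  recs <- tibble::tibble(
    chrom = c("chrA", "chrA", "chrB"),
    start = c(0, 150, 100), end = c(120, 300, 200),
    value = c(4, 8, 99))
  v <- bin_records(recs, ctx, "mean", gap_policy = "missing")$value
  expect_equal(v, c(4, 4, NA, NA, NA, 8, 8, 8, 8, 8))
})

test_that("binning matches the per-base oracle on fuzzed inputs", {
  set.seed(41)
  for (i in 1:120) {
    len <- sample(10:5000, 1)
    start <- sample(0:10000, 1)
    reg <- genomic_region("chrF", start, start + len)
    ctx <- chart_context(reg, sample(1:min(len, 128), 1))
    recs <- random_records(sample(0:40, 1), reg)
    agg <- sample(c("mean", "max", "min", "sum"), 1)
    got <- bin_records(recs, ctx, agg, gap_policy = "missing")$value
    want <- oracle_bin(recs, ctx, agg)
    if (agg %in% c("max", "min")) {
      expect_identical(got, want)
    } else {
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("sum aggregation conserves mass for tiling records", {
  set.seed(42)
  reg <- genomic_region("chrS", 0, 3000)
  edges <- sort(c(0, 3000, sample(1:2999, 30)))
  recs <- tibble::tibble(chrom = "chrS", start = edges[-length(edges)],
                         end = edges[-1],
                         value = round(stats::runif(length(edges) - 1, -5, 5), 2))
  ctx <- chart_context(reg, width_px = 97)
  s <- bin_records(recs, ctx, "sum")
  expect_equal(sum(s$value * (s$end - s$start)),
               sum(recs$value * (recs$end - recs$start)), tolerance = 1e-9)
})

test_that("record order never changes the binned series", {
  set.seed(43)
  reg <- genomic_region("chrP", 0, 2000)
  ctx <- chart_context(reg, 50)
  recs <- random_records(60, reg)
  for (agg in c("mean", "max", "min", "sum")) {
    base <- bin_records(recs, ctx, agg)$value
    for (k in 1:3) {
      perm <- recs[sample(nrow(recs)), ]
      expect_equal(bin_records(perm, ctx, agg)$value, base, tolerance = 1e-12)
    }
  }
})

test_that("unknown aggregators are a configuration error", {
  ctx <- chart_context(genomic_region("chrA", 0, 10), 5)
  expect_error(bin_records(tibble::tibble(), ctx, aggregator = "median"))
})
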