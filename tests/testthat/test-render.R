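# a value_series with prescribed per-column values
make_series <- function(values, ctx, label = "t") {
  stopifnot(length(values) == ctx$width_px)
  s <- tibble::tibble(col = 0:(length(values) - 1L),
                      start = ctx$boundaries[seq_along(values)],
                      end = ctx$boundaries[seq_along(values) + 1L],
                      value = values)
  class(s) <- c("value_series", class(s))
  attr(s, "ctx") <- ctx
  attr(s, "label") <- label
  s
}

test_that("a constant full-scale series renders one darkest rectangle", {
  ctx <- chart_context(genomic_region("chrA", 0, 640), width_px = 64,
                       track_height_px = 16)
  cfg <- horizon_config(n_bands = 4, extent = 50, track_height_px = 16)
  s <- make_series(rep(50, 64), ctx)
  frag <- render_track(track_spec(s, cfg, "t"))
  rects <- regmatches(frag, gregexpr("<rect[^>]*>", frag))[[1]]
  expect_length(rects, 4L) # merged runs: one rect per band
  expect_true(any(grepl(cfg$positive_palette[4], rects, fixed = TRUE)))
  expect_true(all(grepl('width="64"', rects)))
})

test_that("an all-missing series renders an empty fragment", {
  ctx <- chart_context(genomic_region("chrA", 0, 64), width_px = 64)
  cfg <- horizon_config(n_bands = 4, extent = 10)
  s <- make_series(rep(NA_real_, 64), ctx)
  frag <- render_track(track_spec(s, cfg, "t"))
  expect_false(grepl("<rect", frag))
})

test_that("decoding rendered rectangles recovers the clamped values", {
  set.seed(61)
  for (i in 1:8) {
    nb <- sample(1:5, 1)
    ext <- stats::runif(1, 5, 80)
    h <- sample(8:32, 1)
    ctx <- chart_context(genomic_region("chrT", 0, 6400), width_px = 64,
                         track_height_px = h)
    cfg <- horizon_config(n_bands = nb, extent = ext, track_height_px = h)
    v <- round(stats::runif(64, -1.4 * ext, 1.4 * ext), 3)
    s <- make_series(v, ctx)
    svg <- compose_chart(track_spec(s, cfg, "fuzz"), ctx, axis = FALSE)
    got <- decode_chart(svg, cfg, 64)[[1]]
    want <- pmin(pmax(v, -ext), ext)
    quantum <- ext / (nb * h) # one vertical pixel in value units
    expect_lt(max(abs(got - want)), quantum)
  }
})

test_that("offset mode hangs negative stacks from the top edge", {
  ctx <- chart_context(genomic_region("chrA", 0, 4), width_px = 4,
                       track_height_px = 10)
  cfg <- horizon_config(n_bands = 2, extent = 10, mode = "offset",
                        track_height_px = 10)
  s <- make_series(c(-2.5, -2.5, 2.5, 2.5), ctx) # half of band 1
  frag <- render_track(track_spec(s, cfg, "t"))
  rects <- regmatches(frag, gregexpr("<rect[^>]*>", frag))[[1]]
  neg <- rects[grepl("neg", rects)]
  pos <- rects[grepl("pos", rects)]
  expect_true(all(grepl('y="0"', neg)))
  expect_true(all(grepl('y="5"', pos))) # half of 10 px, baseline-anchored
})

test_that("clipped columns are marked with a tick", {
  ctx <- chart_context(genomic_region("chrA", 0, 4), width_px = 4)
  cfg <- horizon_config(n_bands = 2, extent = 10)
  s <- make_series(c(5, 50, 5, 5), ctx)
  frag <- render_track(track_spec(s, cfg, "t"))
  expect_true(grepl('class="clip"', frag))
})

test_that("chart layout height is tracks x (height + gutter) plus the axis", {
  ctx <- chart_context("chr17:1.1M-1.2M", width_px = 100,
                       track_height_px = 20)
  cfg <- horizon_config(n_bands = 4, extent = 40, track_height_px = 20)
  mk <- function(label) track_spec(make_series(rep(10, 100), ctx), cfg, label)

  tracks24 <- lapply(sprintf("s%02d", 1:24), mk)
  svg <- compose_chart(tracks24, ctx, axis = FALSE, gutter = 2)
  expect_match(as.character(svg), 'height="528"') # 24 x 22

  one <- compose_chart(mk("only"), ctx, axis = FALSE, gutter = 2)
  expect_match(as.character(one), 'height="22"')

  with_axis <- compose_chart(mk("only"), ctx, axis = TRUE, gutter = 2)
  expect_match(as.character(with_axis), 'height="40"')
  expect_match(as.character(with_axis), "chr17:1,1[0-9]{2},000")

  expect_error(compose_chart(list(), ctx), "zero tracks")
})

test_that("identical inputs render byte-identical documents", {
  ctx <- chart_context(genomic_region("chrD", 0, 1000), width_px = 50)
  cfg <- horizon_config(n_bands = 4, extent = 9)
  set.seed(62)
  s <- make_series(round(stats::runif(50, -9, 9), 2), ctx)
  t1 <- compose_chart(track_spec(s, cfg, "a"), ctx)
  t2 <- compose_chart(track_spec(s, cfg, "a"), ctx)
  expect_identical(as.character(t1), as.character(t2))

  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  write_svg(t1, p1); write_svg(t2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("mismatched track widths are a composition error", {
  ctx <- chart_context(genomic_region("chrA", 0, 100), width_px = 10)
  ctx2 <- chart_context(genomic_region("chrA", 0, 100), width_px = 20)
  cfg <- horizon_config(n_bands = 2, extent = 1)
  s2 <- make_series(rep(1, 20), ctx2)
  expect_error(compose_chart(track_spec(s2, cfg, "w"), ctx), "columns")
})

test_that("tidy/glance/autoplot expose the chart contents", {
  sim <- simulate_coverage(n_samples = 3, seed = 5)
  ch <- horizon_chart(sim, region = "chr17:1.1M-1.2M", width_px = 100)
  td <- tidy(ch)
  expect_equal(nrow(td), 300L)
  expect_true(all(abs(td$displayed) <= max(ch$extent) + 1e-12))
  gl <- glance(ch)
  expect_equal(gl$n_tracks, 3L)
  expect_equal(gl$width_px, 100L)
  p <- autoplot(ch)
  expect_s3_class(p, "ggplot")
})
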