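# Per-pixel aggregation of interval records: the "metric" series a horizon
# track displays. Semantics are defined per base: where records overlap, a
# base's value is the aggregator applied to all records covering it; a pixel
# column then aggregates its bases. `per_base_expand()` is the brute-force
# reference implementation of exactly that, usable on small regions.

#' Aggregate interval records into one value per pixel column
#'
#' Records may overlap, be unsorted, or extend beyond the context region
#' (they are clipped); records on other chromosomes are ignored. Aggregators:
#' * `mean` — overlap-weighted mean: each base takes the mean of the records
#'   covering it, the column averages its covered bases (uncovered bases do
#'   not dilute the mean).
#' * `max` / `min` — extremum of the values of records overlapping the
#'   column.
#' * `sum` — sum of `value * overlap(column, record)` over records, divided
#'   by the column width in bases (so a record tiling of constant value v
#'   yields v).
#' Columns covered by no record take the `gap_policy` result: `"zero"`
#' (default; for depth-like signal absent coverage is depth 0) or
#' `"missing"` (`NA`, rendered as a blank column).
#'
#' @param records Tibble with `chrom`, `start`, `end`, `value`
#'   (e.g. from [read_bed()]).
#' @param ctx A [chart_context()].
#' @param aggregator One of `"mean"`, `"max"`, `"min"`, `"sum"`.
#' @param gap_policy `"zero"` or `"missing"`.
#' @param label Optional track label carried on the result.
#'
#' @return A `value_series` tibble with one row per pixel column: `col`
#'   (0-based), `start`, `end` (the column's genomic interval) and `value`
#'   (finite, or `NA` for missing); attributes `ctx`, `label`, `aggregator`,
#'   `gap_policy`.
#' @examples
#' ctx <- chart_context(genomic_region("chrA", 0, 10), width_px = 1)
#' recs <- tibble::tibble(chrom = "chrA", start = c(0, 5), end = c(5, 10),
#'                        value = c(10, 20))
#' bin_records(recs, ctx)$value # 15
#' @export
bin_records <- function(records, ctx,
                        aggregator = c("mean", "max", "min", "sum"),
                        gap_policy = c("zero", "missing"), label = NULL) {
  aggregator <- match.arg(aggregator)
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(ctx, "chart_context"))

  rs <- ctx$region$start
  re <- ctx$region$end
  w <- ctx$width_px
  b <- ctx$boundaries

  keep <- records$chrom == ctx$region$chrom &
    records$start < re & records$end > rs
  s <- pmax(records$start[keep], rs)
  e <- pmin(records$end[keep], re)
  v <- records$value[keep]

  values <- rep(NA_real_, w)

  if (length(v) > 0L) {
    if (aggregator %in% c("max", "min")) {
      # column extremum over overlapping records
      c0 <- findInterval(s, b)
      c1 <- findInterval(e - 1, b)
      cols <- unlist(purrr::map2(c0, c1, seq.int), use.names = FALSE)
      vals <- rep(v, c1 - c0 + 1L)
      f <- if (aggregator == "max") max else min
      agg <- tapply(vals, cols, f)
      values[as.integer(names(agg))] <- as.numeric(agg)
    } else {
      # sweep over segments between breakpoints; active sum/count constant
      # within each segment and segments never straddle column boundaries
      pts <- sort(unique(c(b, s, e)))
      pts <- pts[pts >= rs & pts <= re]
      dsum <- dcnt <- numeric(length(pts))
      is_ <- match(s, pts); ie_ <- match(e, pts)
      for (i in seq_along(v)) {
        dsum[is_[i]] <- dsum[is_[i]] + v[i]
        dsum[ie_[i]] <- dsum[ie_[i]] - v[i]
        dcnt[is_[i]] <- dcnt[is_[i]] + 1
        dcnt[ie_[i]] <- dcnt[ie_[i]] - 1
      }
      nseg <- length(pts) - 1L
      active_sum <- cumsum(dsum)[seq_len(nseg)]
      active_cnt <- cumsum(dcnt)[seq_len(nseg)]
      seg_len <- diff(pts)
      seg_col <- findInterval(pts[seq_len(nseg)], b)
      covered <- active_cnt > 0
      if (aggregator == "mean") {
        num <- tapply((active_sum / pmax(active_cnt, 1))[covered] *
                        seg_len[covered], seg_col[covered], sum)
        den <- tapply(seg_len[covered], seg_col[covered], sum)
        values[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
      } else { # sum
        num <- tapply(active_sum[covered] * seg_len[covered],
                      seg_col[covered], sum)
        cols <- as.integer(names(num))
        values[cols] <- as.numeric(num) / (b[cols + 1L] - b[cols])
      }
    }
  }

  if (gap_policy == "zero") values[is.na(values)] <- 0

  out <- tibble::tibble(col = 0:(w - 1L),
                        start = b[seq_len(w)],
                        end = b[seq_len(w) + 1L],
                        value = values)
  class(out) <- c("value_series", class(out))
  attr(out, "ctx") <- ctx
  attr(out, "label") <- label
  attr(out, "aggregator") <- aggregator
  attr(out, "gap_policy") <- gap_policy
  out
}

#' Expand records to per-base values (brute-force oracle)
#'
#' The reference semantics for [bin_records()] at single-base resolution:
#' one slot per base of `region`; overlapping records combine per base by
#' the aggregator (`mean` of covering values, `max`/`min`, or `sum`);
#' uncovered bases are `NA`. Intended for small instances only (region
#' length <= 1e6).
#'
#' @inheritParams bin_records
#' @param region A [genomic_region()].
#' @return Numeric vector of length `region_length(region)`.
#' @examples
#' reg <- genomic_region("chrA", 0, 5)
#' recs <- tibble::tibble(chrom = "chrA", start = 2, end = 4, value = 7)
#' per_base_expand(recs, reg) # NA NA 7 7 NA
#' @export
per_base_expand <- function(records, region,
                            aggregator = c("mean", "max", "min", "sum")) {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(region, "genomic_region"))
  len <- region_length(region)
  if (len > 1e6) {
    stop("per_base_expand is a brute-force oracle for regions <= 1e6 bp; ",
         "got ", len, " bp", call. = FALSE)
  }
  keep <- records$chrom == region$chrom &
    records$start < region$end & records$end > region$start
  s <- pmax(records$start[keep], region$start) - region$start
  e <- pmin(records$end[keep], region$end) - region$start
  v <- records$value[keep]

  acc <- rep(if (aggregator == "max") -Inf else if (aggregator == "min") Inf
             else 0, len)
  cnt <- integer(len)
  for (i in seq_along(v)) {
    idx <- (s[i] + 1L):e[i]
    cnt[idx] <- cnt[idx] + 1L
    acc[idx] <- switch(aggregator,
      mean = , sum = acc[idx] + v[i],
      max = pmax(acc[idx], v[i]),
      min = pmin(acc[idx], v[i]))
  }
  out <- switch(aggregator,
    mean = acc / cnt, # 0/0 -> NaN, fixed below
    sum = acc,
    max = , min = acc)
  out[cnt == 0L] <- NA_real_
  out
}

#' Aggregate per-base values into pixel columns (oracle companion)
#'
#' Applies the per-pixel half of the binning semantics to a per-base vector
#' from [per_base_expand()], giving an independent reference for
#' [bin_records()].
#'
#' @param per_base Numeric vector from [per_base_expand()] over `ctx`'s
#'   region (`NA` = uncovered base).
#' @inheritParams bin_records
#' @return Numeric vector of length `ctx$width_px`.
#' @export
per_base_bin <- function(per_base, ctx,
                         aggregator = c("mean", "max", "min", "sum"),
                         gap_policy = c("zero", "missing")) {
  aggregator <- match.arg(aggregator)
  gap_policy <- match.arg(gap_policy)
  stopifnot(length(per_base) == region_length(ctx$region))
  rel <- ctx$boundaries - ctx$region$start
  out <- vapply(seq_len(ctx$width_px), function(i) {
    p <- per_base[(rel[i] + 1L):rel[i + 1L]]
    cov <- p[!is.na(p)]
    if (length(cov) == 0L) return(NA_real_)
    switch(aggregator,
      mean = mean(cov),
      max = max(cov),
      min = min(cov),
      sum = sum(cov) / length(p))
  }, numeric(1))
  if (gap_policy == "zero") out[is.na(out)] <- 0
  out
}
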