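# Coordinate model: regions are 0-based, half-open, matching BED.

round_half_up <- function(x) floor(x + 0.5)

#' Create a genomic region
#'
#' A region is the scope of a chart: one chromosome plus a half-open,
#' 0-based coordinate interval `[start, end)`.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start position.
#' @param end Exclusive end position; must satisfy `start < end`.
#'
#' @return An object of class `genomic_region` with fields `chrom`, `start`,
#'   `end`.
#' @examples
#' genomic_region("chr17", 1100000, 1200000)
#' @export
genomic_region <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) ||
      !nzchar(chrom)) {
    stop("`chrom` must be a single non-empty string", call. = FALSE)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("`start` and `end` must be single numbers", call. = FALSE)
  }
  if (start != trunc(start) || end != trunc(end)) {
    stop("`start` and `end` must be whole numbers", call. = FALSE)
  }
  if (start < 0 || start >= end) {
    stop("need 0 <= start < end, got [", start, ", ", end, ")", call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(format_region(x), "\n", sep = "")
  invisible(x)
}

#' Region length in bases
#' @param region A [genomic_region()].
#' @return Number of bases, `end - start`.
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "genomic_region"))
  region$end - region$start
}

#' Format a region as `chrom:start-end`
#' @param region A [genomic_region()].
#' @return A string such as `"chr17:1100000-1200000"`.
#' @export
format_region <- function(region) {
  sprintf("%s:%d-%d", region$chrom, region$start, region$end)
}

# Parse one coordinate token: digit separators "," and "_", optional k/M/G
# suffix with decimals (1.1M -> 1100000).
parse_coord <- function(token) {
  token <- gsub("[,_]", "", trimws(token))
  m <- regmatches(token, regexec("^([0-9]*\\.?[0-9]+)([kKmMgG]?)$", token))[[1]]
  if (length(m) == 0L) return(NA_real_)
  mult <- switch(tolower(m[3]), "k" = 1e3, "m" = 1e6, "g" = 1e9, 1)
  val <- as.numeric(m[2]) * mult
  if (val != trunc(val)) return(NA_real_)
  val
}

#' Parse a region string
#'
#' Accepts `chrom:start-end` with optional `,`/`_` digit separators and
#' `k`/`M`/`G` suffixes, e.g. `"chr17:1.1M-1.2M"` or
#' `"chr17:1,100,000-1,200,000"`. Coordinates are interpreted as 0-based
#' half-open.
#'
#' @param x Region string.
#' @return A [genomic_region()].
#' @examples
#' parse_region("chr17:1.1M-1.2M")
#' @export
parse_region <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("region must be a single string", call. = FALSE)
  }
  i <- regexpr(":[^:]*$", x)
  if (i < 2L) {
    stop("cannot parse region string '", x, "': expected chrom:start-end",
         call. = FALSE)
  }
  chrom <- substr(x, 1L, i - 1L)
  range <- substr(x, i + 1L, nchar(x))
  parts <- strsplit(range, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("cannot parse region string '", x, "': expected chrom:start-end",
         call. = FALSE)
  }
  start <- parse_coord(parts[1])
  end <- parse_coord(parts[2])
  if (is.na(start) || is.na(end)) {
    stop("cannot parse coordinates in region string '", x, "'", call. = FALSE)
  }
  genomic_region(chrom, start, end)
}

#' Create a chart context
#'
#' The context pins the genomic region under study and the pixel budget of
#' the chart: `width_px` columns horizontally, `track_height_px` vertical
#' pixels per track. Each pixel column covers `step_bp = length / width_px`
#' bases. When `width_px` exceeds the region length it is reduced to the
#' region length (one base per column) with a warning, so no column ever
#' covers zero bases.
#'
#' @param region A [genomic_region()] or region string for [parse_region()].
#' @param width_px Number of pixel columns (integer >= 1).
#' @param track_height_px Vertical pixels per track (integer >= 2).
#'
#' @return An object of class `chart_context` with fields `region`,
#'   `width_px`, `track_height_px`, `step_bp` and the precomputed column
#'   `boundaries` (length `width_px + 1`).
#' @examples
#' ctx <- chart_context("chr17:1.1M-1.2M", width_px = 100)
#' ctx$step_bp
#' @export
chart_context <- function(region, width_px, track_height_px = 20L) {
  if (is.character(region)) region <- parse_region(region)
  stopifnot(inherits(region, "genomic_region"))
  width_px <- as.integer(width_px)
  track_height_px <- as.integer(track_height_px)
  if (is.na(width_px) || width_px < 1L) {
    stop("`width_px` must be an integer >= 1", call. = FALSE)
  }
  if (is.na(track_height_px) || track_height_px < 2L) {
    stop("`track_height_px` must be an integer >= 2", call. = FALSE)
  }
  len <- region_length(region)
  if (width_px > len) {
    warning("width_px (", width_px, ") exceeds region length (", len,
            "); reducing to one column per base", call. = FALSE)
    width_px <- as.integer(len)
  }
  step_bp <- len / width_px
  boundaries <- region$start + round_half_up((0:width_px) * step_bp)
  boundaries[width_px + 1L] <- region$end # last column absorbs remainder
  structure(
    list(region = region, width_px = width_px,
         track_height_px = track_height_px, step_bp = step_bp,
         boundaries = boundaries),
    class = "chart_context"
  )
}

#' @export
print.chart_context <- function(x, ...) {
  cat(sprintf("<chart_context> %s | %d px wide (%.3f bp/px), track height %d px\n",
              format_region(x$region), x$width_px, x$step_bp,
              x$track_height_px))
  invisible(x)
}

#' Genomic interval covered by pixel columns
#'
#' Maps pixel columns to the half-open genomic sub-intervals they cover.
#' Column intervals tile the context region exactly: no gaps, no overlaps.
#'
#' @param ctx A [chart_context()].
#' @param col Pixel column index (0-based), vectorised; each must satisfy
#'   `0 <= col < ctx$width_px`.
#' @return A tibble with one row per input column: `col`, `chrom`, `start`,
#'   `end`.
#' @examples
#' ctx <- chart_context("chr17:1.1M-1.2M", width_px = 100)
#' pixel_to_interval(ctx, 0)
#' @export
pixel_to_interval <- function(ctx, col) {
  stopifnot(inherits(ctx, "chart_context"))
  col <- as.integer(col)
  if (any(is.na(col)) || any(col < 0L) || any(col >= ctx$width_px)) {
    stop("pixel column out of range [0, ", ctx$width_px, ")", call. = FALSE)
  }
  tibble::tibble(
    col = col,
    chrom = ctx$region$chrom,
    start = ctx$boundaries[col + 1L],
    end = ctx$boundaries[col + 2L]
  )
}

#' Pixel columns overlapping a genomic interval
#'
#' Returns the half-open range `[from, to)` of 0-based pixel columns whose
#' intervals overlap `iv`. An interval with no overlap yields an empty range
#' (`from == to`); a chromosome mismatch is an error.
#'
#' @param ctx A [chart_context()].
#' @param iv A [genomic_region()] on the context's chromosome.
#' @return Named integer vector `c(from, to)`, half-open.
#' @examples
#' ctx <- chart_context(genomic_region("chrA", 0, 10), width_px = 10)
#' interval_to_pixels(ctx, genomic_region("chrA", 3, 5))
#' @export
interval_to_pixels <- function(ctx, iv) {
  stopifnot(inherits(ctx, "chart_context"), inherits(iv, "genomic_region"))
  if (iv$chrom != ctx$region$chrom) {
    stop("chromosome mismatch: context is ", ctx$region$chrom,
         ", interval is ", iv$chrom, call. = FALSE)
  }
  b <- ctx$boundaries
  w <- ctx$width_px
  hit <- which(b[seq_len(w)] < iv$end & b[seq_len(w) + 1L] > iv$start)
  if (length(hit) == 0L) {
    return(c(from = 0L, to = 0L))
  }
  c(from = hit[1L] - 1L, to = hit[length(hit)])
}
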