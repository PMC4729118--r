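# High-level chart construction: tidy records in, a renderable chart out.

#' Build a multi-track horizon chart from tidy records
#'
#' The main entry point: takes records for one or more samples, bins each
#' sample's records into one value per pixel column, and bundles the
#' resulting tracks with a shared horizon configuration. By default the
#' extent (the value at which the colour ramp saturates) is the chart-wide
#' maximum absolute binned value, so all tracks share one colour scale and
#' are directly cross-comparable — the property that makes a stack of
#' horizon tracks useful for multi-sample QC. Per-track extents are
#' available with `extent_scope = "track"`.
#'
#' @param records A tibble with columns `chrom`, `start`, `end`, `value`
#'   and (for multi-sample charts) `sample`; or a named list of per-sample
#'   record tibbles.
#' @param region A [genomic_region()] or region string (the chart
#'   "context" scope).
#' @param width_px Chart width in pixel columns.
#' @param track_height_px Vertical pixels per collapsed track.
#' @param n_bands,mode,positive_palette,negative_palette Passed to
#'   [horizon_config()].
#' @param extent `"auto"` (chart-wide max absolute binned value), or a
#'   positive number.
#' @param extent_scope `"chart"` (shared extent, default) or `"track"`.
#' @param aggregator,gap_policy Passed to [bin_records()].
#' @return An object of class `horizon_chart`: list with `ctx`, `tracks`
#'   (list of [track_spec()]), `extent`, `params`.
#' @examples
#' sim <- simulate_coverage(n_samples = 3, seed = 1)
#' chart <- horizon_chart(sim, region = "chr17:1.1M-1.2M", width_px = 200)
#' glance(chart)
#' @export
horizon_chart <- function(records, region, width_px = 800L,
                          track_height_px = 20L, n_bands = 4L,
                          mode = c("mirror", "offset"), extent = "auto",
                          extent_scope = c("chart", "track"),
                          aggregator = "mean", gap_policy = "zero",
                          positive_palette = NULL, negative_palette = NULL) {
  mode <- match.arg(mode)
  extent_scope <- match.arg(extent_scope)
  ctx <- chart_context(region, width_px, track_height_px)

  if (is.data.frame(records)) {
    if (!"sample" %in% names(records)) records$sample <- "track"
    per_sample <- split(records, factor(records$sample,
                                        levels = unique(records$sample)))
  } else {
    per_sample <- records
    if (is.null(names(per_sample)) || any(!nzchar(names(per_sample)))) {
      stop("a list of record tables must be named by sample", call. = FALSE)
    }
  }

  series <- purrr::imap(per_sample, function(recs, id) {
    bin_records(recs, ctx, aggregator = aggregator, gap_policy = gap_policy,
                label = id)
  })

  track_max <- purrr::map_dbl(series, function(s) {
    m <- suppressWarnings(max(abs(s$value), na.rm = TRUE))
    if (!is.finite(m)) 0 else m
  })
  resolve_extent <- function(m) {
    if (identical(extent, "auto")) {
      if (m <= 0) 1 else m
    } else {
      as.numeric(extent)
    }
  }

  tracks <- purrr::imap(series, function(s, id) {
    m <- if (extent_scope == "chart") max(track_max) else track_max[[id]]
    cfg <- horizon_config(n_bands = n_bands, extent = resolve_extent(m),
                          mode = mode, positive_palette = positive_palette,
                          negative_palette = negative_palette,
                          track_height_px = track_height_px)
    track_spec(s, cfg, label = id)
  })

  structure(
    list(ctx = ctx, tracks = unname(tracks),
         extent = vapply(tracks, function(t) t$cfg$extent, numeric(1)),
         params = list(aggregator = aggregator, gap_policy = gap_policy,
                       n_bands = n_bands, mode = mode,
                       extent_scope = extent_scope)),
    class = "horizon_chart"
  )
}

#' @export
print.horizon_chart <- function(x, ...) {
  cat(sprintf("<horizon_chart> %s | %d track(s), %d px wide, extent %s\n",
              format_region(x$ctx$region), length(x$tracks), x$ctx$width_px,
              paste(signif(unique(x$extent), 4), collapse = "/")))
  invisible(x)
}

#' Render a horizon chart to SVG
#'
#' @param chart A [horizon_chart()].
#' @param axis,gutter,label_width Passed to [compose_chart()].
#' @return A `horizon_svg` string.
#' @export
render_chart <- function(chart, axis = TRUE, gutter = 2L, label_width = 80L) {
  stopifnot(inherits(chart, "horizon_chart"))
  compose_chart(chart$tracks, chart$ctx, axis = axis, gutter = gutter,
                label_width = label_width)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a horizon chart into per-column values
#'
#' One row per (track, pixel column) with the binned value and the value
#' the rendered chart displays (the binned value clamped at the extent) —
#' the pair a reproducibility spot-check compares.
#'
#' @param x A [horizon_chart()].
#' @param ... Unused.
#' @return A tibble: `sample`, `col`, `start`, `end`, `value`,
#'   `displayed`, `clipped`.
#' @export
tidy.horizon_chart <- function(x, ...) {
  purrr::map_dfr(x$tracks, function(t) {
    v <- t$series$value
    ext <- t$cfg$extent
    tibble::tibble(
      sample = t$label,
      col = t$series$col,
      start = t$series$start,
      end = t$series$end,
      value = v,
      displayed = pmin(pmax(v, -ext), ext),
      clipped = !is.na(v) & abs(v) > ext
    )
  })
}

#' One-row chart summary
#'
#' @param x A [horizon_chart()].
#' @param ... Unused.
#' @return A tibble with `region`, `n_tracks`, `width_px`,
#'   `track_height_px`, `n_bands`, `mode`, `extent` (chart-wide max),
#'   `aggregator`.
#' @export
glance.horizon_chart <- function(x, ...) {
  tibble::tibble(
    region = format_region(x$ctx$region),
    n_tracks = length(x$tracks),
    width_px = x$ctx$width_px,
    track_height_px = x$ctx$track_height_px,
    n_bands = x$params$n_bands,
    mode = x$params$mode,
    extent = max(x$extent),
    aggregator = x$params$aggregator
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a horizon chart with ggplot2
#'
#' A ggplot rendering of the same collapsed-band geometry the SVG renderer
#' draws; convenient for interactive inspection. (The SVG path, not this
#' one, is the byte-deterministic output.)
#'
#' @param object A [horizon_chart()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.horizon_chart <- function(object, ...) {
  rects <- purrr::map_dfr(object$tracks, function(t) {
    cfg <- t$cfg
    dec <- horizon_decompose(t$series$value, cfg) |>
      dplyr::filter(.data$fill > 0, .data$sign != 0)
    if (nrow(dec) == 0L) return(NULL)
    dec |>
      dplyr::mutate(
        sample = t$label,
        xmin = t$series$start[.data$index],
        xmax = t$series$end[.data$index],
        ymin = 0,
        ymax = .data$fill,
        colour = band_color(.data$sign, .data$fill, .data$band, cfg)
      )
  })
  p <- ggplot2::ggplot(rects)
  if (nrow(rects) > 0L) {
    p <- p + ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      fill = rects$colour
    )
  }
  p +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$sample), switch = "y") +
    ggplot2::scale_y_continuous(breaks = NULL, expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = object$ctx$region$chrom, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing.y = ggplot2::unit(1, "pt"),
                   strip.text.y.left = ggplot2::element_text(angle = 0))
}
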