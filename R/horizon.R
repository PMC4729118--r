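# The horizon transform: slice the value range into bands, colour by a
# light-to-dark ramp with hue encoding sign, mirror negatives over the
# baseline (halving the vertical space), and collapse all bands onto the
# baseline (a further n_bands-fold reduction). The transform is invertible
# up to clamping at the extent, which is what makes spot-checking rendered
# pixels against raw input mechanical.

default_positive_palette <- c("#c7e9c0", "#a1d99b", "#41ab5d", "#006d2c")
default_negative_palette <- c("#c6dbef", "#9ecae1", "#4292c6", "#08519c")

ramp_palette <- function(base, n) {
  if (n == length(base)) return(base)
  grDevices::colorRampPalette(base)(n)
}

#' Horizon track configuration
#'
#' @param n_bands Number of bands (integer >= 1); each band spans
#'   `extent / n_bands` value units. Default 4.
#' @param extent Clamp value V > 0: values are displayed within `[-V, +V]`,
#'   beyond which they saturate the top band (and are flagged clipped).
#' @param mode `"mirror"` (negatives flipped over the baseline, the
#'   default) or `"offset"` (negatives hang from the top edge).
#' @param positive_palette,negative_palette Colours, light to dark, one per
#'   band. Defaults: greens for positive (read depth is non-negative, so a
#'   depth chart shows only green hues), blues for negative. Palettes of
#'   length 4 are interpolated when `n_bands != 4`.
#' @param track_height_px Vertical pixels for the collapsed track
#'   (integer >= 2).
#' @return An object of class `horizon_config`.
#' @examples
#' horizon_config(n_bands = 4, extent = 100)
#' @export
horizon_config <- function(n_bands = 4L, extent = 1,
                           mode = c("mirror", "offset"),
                           positive_palette = NULL, negative_palette = NULL,
                           track_height_px = 20L) {
  mode <- match.arg(mode)
  n_bands <- as.integer(n_bands)
  if (is.na(n_bands) || n_bands < 1L) {
    stop("`n_bands` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(extent) || length(extent) != 1L || !is.finite(extent) ||
      extent <= 0) {
    stop("`extent` must be a positive finite number", call. = FALSE)
  }
  track_height_px <- as.integer(track_height_px)
  if (is.na(track_height_px) || track_height_px < 2L) {
    stop("`track_height_px` must be an integer >= 2", call. = FALSE)
  }
  pos <- if (is.null(positive_palette)) {
    ramp_palette(default_positive_palette, n_bands)
  } else positive_palette
  neg <- if (is.null(negative_palette)) {
    ramp_palette(default_negative_palette, n_bands)
  } else negative_palette
  if (length(pos) != n_bands || length(neg) != n_bands) {
    stop("palettes must have exactly `n_bands` colours", call. = FALSE)
  }
  structure(list(n_bands = n_bands, extent = extent, mode = mode,
                 positive_palette = pos, negative_palette = neg,
                 track_height_px = track_height_px),
            class = "horizon_config")
}

#' @export
print.horizon_config <- function(x, ...) {
  cat(sprintf("<horizon_config> %d bands, extent %g, %s mode, %d px tall\n",
              x$n_bands, x$extent, x$mode, x$track_height_px))
  invisible(x)
}

#' Decompose values into horizon band stacks
#'
#' For each finite value v, with band unit `u = extent / n_bands` and
#' `s = min(|v|, extent) / u`, band i (1-based) gets fill
#' `clamp(s - (i - 1), 0, 1)`: all bands below the value are full, at most
#' one band is partial, all above are empty. Sign is `sign(v)`; values with
#' `|v| > extent` saturate and are flagged `clipped`. Missing (`NA`) input
#' yields sign 0, all fills 0 and `missing = TRUE`.
#'
#' @param values Numeric vector (may contain `NA`), e.g. a `value_series`
#'   `value` column.
#' @param cfg A [horizon_config()].
#' @return A tibble in long form, one row per (value, band):
#'   `index` (1-based position in `values`), `value`, `sign`, `clipped`,
#'   `missing`, `band` (1-based), `fill` in `[0, 1]`.
#' @examples
#' cfg <- horizon_config(n_bands = 4, extent = 100)
#' horizon_decompose(-37.5, cfg)$fill # 1, 0.5, 0, 0
#' @export
horizon_decompose <- function(values, cfg) {
  stopifnot(inherits(cfg, "horizon_config"))
  n <- length(values)
  nb <- cfg$n_bands
  unit <- cfg$extent / nb
  missing <- is.na(values)
  v <- ifelse(missing, 0, values)
  s <- pmin(abs(v), cfg$extent) / unit
  # rows: index varies slowest, band fastest
  fill <- pmin(pmax(rep(s, each = nb) - (rep.int(seq_len(nb), n) - 1), 0), 1)
  tibble::tibble(
    index = rep(seq_len(n), each = nb),
    value = rep(values, each = nb),
    sign = rep(ifelse(missing, 0, sign(v)), each = nb),
    clipped = rep(!missing & abs(v) > cfg$extent, each = nb),
    missing = rep(missing, each = nb),
    band = rep.int(seq_len(nb), n),
    fill = fill
  )
}

# Reshape a long stack tibble into an n_bands x n fill matrix (bands in
# rows), erroring if any stack is ragged.
stack_matrix <- function(stack, cfg) {
  nb <- cfg$n_bands
  o <- order(stack$index, stack$band)
  st <- stack[o, ]
  n <- length(unique(st$index))
  if (nrow(st) != n * nb ||
      !all(st$band == rep.int(seq_len(nb), n))) {
    stop("invalid band stack: expected ", nb, " bands per index",
         call. = FALSE)
  }
  list(fills = matrix(st$fill, nrow = nb),
       sign = st$sign[seq(1, nrow(st), by = nb)],
       missing = st$missing[seq(1, nrow(st), by = nb)])
}

validate_stack <- function(m, cfg, tol = 1e-9) {
  f <- m$fills
  if (any(f < -tol | f > 1 + tol)) {
    stop("invalid band stack: fills must lie in [0, 1]", call. = FALSE)
  }
  nb <- nrow(f)
  # a valid stack per column is (1, ..., 1, partial, 0, ..., 0): every fill
  # strictly below any non-full band must be zero
  if (nb > 1L) {
    nonfull_above <- apply(f < 1 - tol, 2, cumsum)[-nb, , drop = FALSE]
    must_be_zero <- rbind(FALSE, nonfull_above >= 1)
    if (any(f[must_be_zero] > tol)) {
      stop("invalid band stack: at most one partial band is allowed, with ",
           "all lower bands full and all higher bands empty", call. = FALSE)
    }
  }
  if (any(f[, m$sign == 0, drop = FALSE] > tol)) {
    stop("invalid band stack: sign 0 implies all fills 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Reconstruct values from band stacks
#'
#' The inverse of [horizon_decompose()]: each stack yields
#' `sign * (extent / n_bands) * sum(fill)`. For any finite v,
#' `horizon_reconstruct(horizon_decompose(v, cfg), cfg)` equals
#' `clamp(v, -extent, +extent)` to floating round-off. Missing stacks
#' reconstruct to `NA`. Stacks violating the band-stack invariants are an
#' error.
#'
#' @param stack Long tibble as produced by [horizon_decompose()].
#' @param cfg The matching [horizon_config()].
#' @return Numeric vector, one value per distinct `index`.
#' @export
horizon_reconstruct <- function(stack, cfg) {
  stopifnot(inherits(cfg, "horizon_config"))
  m <- stack_matrix(stack, cfg)
  validate_stack(m, cfg)
  unit <- cfg$extent / cfg$n_bands
  v <- m$sign * unit * colSums(m$fills)
  v[m$missing] <- NA_real_
  v
}

#' Colour of one band of a stack
#'
#' Positive stacks draw from the positive palette, negative stacks from the
#' negative palette; an empty band (fill 0) has no colour (`NA`). Hence an
#' all-non-negative series (e.g. read depth) only ever shows positive-hue
#' colours.
#'
#' @param sign,fill,band Vectors (recycled) of stack sign, band fill and
#'   1-based band index.
#' @param cfg A [horizon_config()].
#' @return Character vector of colours, `NA` where the band is empty.
#' @export
band_color <- function(sign, fill, band, cfg) {
  stopifnot(inherits(cfg, "horizon_config"))
  if (any(band < 1L | band > cfg$n_bands)) {
    stop("band index out of range [1, ", cfg$n_bands, "]", call. = FALSE)
  }
  dplyr::case_when(
    fill <= 0 ~ NA_character_,
    sign > 0 ~ cfg$positive_palette[band],
    sign < 0 ~ cfg$negative_palette[band],
    .default = NA_character_
  )
}

#' Plot-area height required at a given rendering stage
#'
#' At equal per-pixel value resolution (`band_height_px` vertical pixels
#' per band of value range), the pre-mirror stage (positive bands above the
#' baseline, negative below) needs `2 * n_bands * band_height_px`; after
#' mirroring negatives over the baseline it needs `n_bands *
#' band_height_px` — exactly half; collapsing the bands onto the baseline
#' reduces the one-sided span a further `n_bands`-fold to
#' `band_height_px`.
#'
#' @param cfg A [horizon_config()] (supplies `n_bands`).
#' @param band_height_px Vertical pixels per band (integer >= 1).
#' @param stage `"pre_mirror"`, `"mirror"`, or `"collapsed"`.
#' @return Height in pixels.
#' @examples
#' cfg <- horizon_config(n_bands = 4)
#' vertical_span(cfg, 6, "pre_mirror") / vertical_span(cfg, 6, "mirror") # 2
#' @export
vertical_span <- function(cfg, band_height_px,
                          stage = c("pre_mirror", "mirror", "collapsed")) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "horizon_config"))
  band_height_px <- as.integer(band_height_px)
  if (is.na(band_height_px) || band_height_px < 1L) {
    stop("`band_height_px` must be an integer >= 1", call. = FALSE)
  }
  switch(stage,
    pre_mirror = 2L * cfg$n_bands * band_height_px,
    mirror = cfg$n_bands * band_height_px,
    collapsed = band_height_px
  )
}
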