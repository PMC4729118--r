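# Synthetic multi-sample coverage: the package's demonstration scenario is
# a 24-sample ~30x whole-genome QC view of a 100 kb window, with coverage
# dropouts shared by every sample and one sample whose depth is globally
# low. The noise model is a truncated Gaussian on window means, not
# per-read Poisson sampling: the generator exercises visualization and
# plumbing, and smooth depth-like noise suffices for that.

#' Default shared-dropout intervals for a region
#'
#' Two sub-intervals (at 30–40% and 60–65% of the region) whose coverage
#' is scaled by `multiplier` in every sample — emulating regions
#' consistently underrepresented across samples.
#'
#' @param region A [genomic_region()].
#' @param multiplier Depth multiplier inside the dropouts, in `[0, 1)`.
#' @return Tibble with `start`, `end`, `multiplier`.
#' @export
default_dropouts <- function(region, multiplier = 0.2) {
  len <- region_length(region)
  at <- function(f) region$start + round(f * len)
  tibble::tibble(
    start = c(at(0.30), at(0.60)),
    end = c(at(0.40), at(0.65)),
    multiplier = multiplier
  )
}

#' Simulate multi-sample read-depth records
#'
#' Generates per-sample BedGraph-style records tiling `region` in windows
#' of `window_bp`, with window value
#' `mean_depth * dropout multiplier * per-sample factor + N(0, noise_sd)`,
#' truncated at 0 (depth is non-negative). Windows straddling a dropout
#' boundary get an overlap-weighted multiplier. One designated sample has
#' its whole-region depth scaled by `low_sample_factor`, the globally
#' low-coverage sample a QC view should flag. Deterministic given `seed`.
#'
#' @param n_samples Number of samples (default 24).
#' @param region A [genomic_region()] or region string (default
#'   `"chr17:1.1M-1.2M"`, a 100 kb window).
#' @param mean_depth Mean read depth (default 30).
#' @param noise_sd Gaussian noise SD on window means; default
#'   `sqrt(mean_depth)`, the dispersion of Poisson-like depth.
#' @param dropouts Tibble of shared dropout intervals (`start`, `end`,
#'   `multiplier`), or `NULL` for none. Default: [default_dropouts()] with
#'   multiplier 0.2.
#' @param low_sample_index 1-based index of the globally low sample, or
#'   `NA` for none. Default: the last sample.
#' @param low_sample_factor Whole-region depth factor for that sample
#'   (default 0.3).
#' @param window_bp Record width in bases (default 100).
#' @param seed Integer seed (default 1).
#' @return A tibble `sample`, `chrom`, `start`, `end`, `value`, sorted by
#'   sample then start; records tile the region exactly. Attribute `spec`
#'   holds the simulation parameters.
#' @examples
#' sim <- simulate_coverage(n_samples = 3, seed = 7)
#' dplyr::count(sim, sample)
#' @export
simulate_coverage <- function(n_samples = 24L,
                              region = "chr17:1.1M-1.2M",
                              mean_depth = 30,
                              noise_sd = sqrt(mean_depth),
                              dropouts = default_dropouts(region_obj),
                              low_sample_index = n_samples,
                              low_sample_factor = 0.3,
                              window_bp = 100L,
                              seed = 1L) {
  if (is.character(region)) region <- parse_region(region)
  stopifnot(inherits(region, "genomic_region"))
  region_obj <- region
  n_samples <- as.integer(n_samples)
  window_bp <- as.integer(window_bp)
  if (is.na(n_samples) || n_samples < 1L) {
    stop("`n_samples` must be >= 1", call. = FALSE)
  }
  if (is.na(window_bp) || window_bp < 1L) {
    stop("`window_bp` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    stop("`mean_depth` must be positive", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  dropouts <- force(dropouts)
  if (!is.null(dropouts)) {
    stopifnot(all(c("start", "end", "multiplier") %in% names(dropouts)))
    if (any(dropouts$start < region$start | dropouts$end > region$end |
            dropouts$start >= dropouts$end)) {
      stop("dropout intervals must lie within the region", call. = FALSE)
    }
    if (any(dropouts$multiplier < 0 | dropouts$multiplier >= 1)) {
      stop("dropout multipliers must lie in [0, 1)", call. = FALSE)
    }
  }
  if (!is.na(low_sample_index) &&
      (low_sample_index < 1L || low_sample_index > n_samples)) {
    stop("`low_sample_index` out of range", call. = FALSE)
  }

  starts <- seq(region$start, region$end - 1L, by = window_bp)
  ends <- pmin(starts + window_bp, region$end)
  nw <- length(starts)

  # overlap-weighted dropout multiplier per window
  mult <- rep(1, nw)
  if (!is.null(dropouts) && nrow(dropouts) > 0L) {
    for (i in seq_len(nrow(dropouts))) {
      ov <- pmax(0, pmin(ends, dropouts$end[i]) - pmax(starts, dropouts$start[i]))
      mult <- mult * (1 - (1 - dropouts$multiplier[i]) * ov / (ends - starts))
    }
  }

  sample_ids <- sprintf("sample%02d", seq_len(n_samples))
  factors <- rep(1, n_samples)
  if (!is.na(low_sample_index)) {
    factors[low_sample_index] <- low_sample_factor
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))

  out <- purrr::map_dfr(seq_len(n_samples), function(i) {
    v <- pmax(0, mean_depth * mult * factors[i] + stats::rnorm(nw, 0, noise_sd))
    tibble::tibble(sample = sample_ids[i], chrom = region$chrom,
                   start = starts, end = ends, value = v)
  })
  attr(out, "spec") <- list(
    n_samples = n_samples, region = region, mean_depth = mean_depth,
    noise_sd = noise_sd, dropouts = dropouts,
    low_sample_index = low_sample_index,
    low_sample_factor = low_sample_factor, window_bp = window_bp,
    seed = seed, sample_ids = sample_ids
  )
  out
}

#' Write simulated coverage as one BED file per sample
#'
#' Emits sorted 4-column BedGraph files (`<sample>.bed`) plus a
#' `manifest.json` describing the simulation, ready for
#' [bedfile_source()], [build_index()] or [serve_bed()].
#'
#' @param sim Tibble from [simulate_coverage()] (any tibble with a
#'   `sample` column works).
#' @param dir Output directory (created if needed).
#' @return (Invisibly) character vector of the BED paths written.
#' @export
write_coverage <- function(sim, dir) {
  stopifnot("sample" %in% names(sim))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(sim$sample)
  paths <- vapply(ids, function(id) {
    p <- file.path(dir, paste0(id, ".bed"))
    recs <- dplyr::arrange(sim[sim$sample == id, ], .data$chrom, .data$start)
    write_bed(recs, p)
    p
  }, "")
  spec <- attr(sim, "spec")
  manifest <- list(samples = as.list(ids))
  if (!is.null(spec)) {
    manifest$region <- format_region(spec$region)
    manifest$mean_depth <- spec$mean_depth
    manifest$noise_sd <- spec$noise_sd
    manifest$window_bp <- spec$window_bp
    manifest$seed <- spec$seed
    if (!is.na(spec$low_sample_index)) {
      manifest$low_sample <- spec$sample_ids[spec$low_sample_index]
      manifest$low_sample_factor <- spec$low_sample_factor
    }
    if (!is.null(spec$dropouts)) {
      manifest$dropouts <- spec$dropouts
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(unname(paths))
}
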