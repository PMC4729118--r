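---
title: "Horizon charts for genomic signal: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Horizon charts for genomic signal: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(horizonbed)
```

# The visualization model

A horizon chart compresses a signed quantitative signal into a fixed-height
strip in three steps. Starting from a filled area chart with hue encoding
sign, the value range `[-V, +V]` is divided into `n` bands of `V/n` value
units each, coloured light to dark; negative values are then mirrored over
the baseline, halving the vertical space needed at equal per-pixel value
resolution; finally all bands are collapsed onto the baseline, overplotted
so that darker (higher) bands cover lighter ones — a further `n`-fold
reduction. `vertical_span()` states this arithmetic: a two-sided banded
chart needs `2·n·h` pixels where the collapsed horizon track needs `h`.

For genomic data the x-axis is a chromosome interval rather than time.
The chart **context** (`chart_context()`) pins a region and a pixel
budget; a data **source** answers region queries; per-pixel binning turns
overlapping interval records into one value per pixel column (the
**metric**); the horizon transform and renderer draw it.

The band decomposition is deliberately invertible. With band unit
`u = V/n` and `s = min(|v|, V)/u`, band `i` gets fill
`clamp(s − (i−1), 0, 1)`, so a valid stack is always
`(1, …, 1, partial, 0, …, 0)`, and

```
reconstruct(decompose(v)) = sign(v) · u · Σ fill_i = clamp(v, −V, +V).
```

`decode_chart()` applies the inverse to the rectangles of a rendered SVG,
so a rendered chart can be checked mechanically against the raw input —
the package's reproducibility property, exercised in the test suite and
in `scripts/acceptance.R`.

```{r roundtrip}
cfg <- horizon_config(n_bands = 4, extent = 100)
horizon_decompose(-37.5, cfg)$fill
horizon_reconstruct(horizon_decompose(-37.5, cfg), cfg)
```

# Coordinate conventions

All coordinates are 0-based, half-open — the BED convention — in every
data structure and in region strings (`"chr17:1.1M-1.2M"` means
`[1100000, 1200000)`). Axis tick labels reuse the same convention as the
region strings, so a region entered as `1.1M` shows ticks at `1,100,000`
rather than an off-by-one 1-based rendering; the chart's audience reads
the labels against the strings they typed.

Pixel column `c` of a `w`-column context over a region of length `L`
covers `start + round(c·L/w)` to `start + round((c+1)·L/w)` (round half
up), which tiles the region exactly with no gaps or overlaps; the last
column absorbs any rounding remainder. Requesting more columns than bases
would create empty columns, so the width is clamped to one column per
base with a warning.

# Binning semantics

Binning is defined per base, which makes overlapping records
well-defined and order-free: each base takes the aggregator of all
records covering it, then a pixel column aggregates its bases.

* `mean` (default): the column averages its *covered* bases — uncovered
  bases do not dilute the mean. Depth is an intensive quantity, so the
  overlap-weighted mean is the faithful reduction to fewer pixels.
* `max`/`min`: extremum over records overlapping the column (identical to
  the per-base formulation).
* `sum`: per-base sums averaged over the *full* column width, so a tiling
  of constant value reproduces that constant and
  `Σ value·width` is conserved for non-overlapping tilings.

Uncovered columns take the `gap_policy`: `"zero"` by default, because for
depth-like data absence of coverage *is* depth 0; `"missing"` renders a
blank column instead. A consequence worth knowing: a missing column and a
true value of 0 both draw no rectangles; only the upstream gap policy
distinguishes them.

The production path computes this with a segment sweep (record endpoints
and column boundaries split the region into constant segments), while
`per_base_expand()`/`per_base_bin()` are the brute-force reference for
regions up to 1 Mb. The two are compared exactly for `max`/`min` and at
1e-9 relative tolerance for `mean`/`sum` over hundreds of fuzzed cases.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_bands` | 4 | bands per track; more bands = more value resolution, subtler colours |
| `extent` | `"auto"` | clamp value `V` (value units, e.g. depth); auto = chart-wide max |v| |
| `mode` | `"mirror"` | negatives flipped over the baseline; `"offset"` hangs them from the top edge |
| `track_height_px` | 20 | collapsed track height (pixels) |
| `width_px` | 800 | pixel columns; each covers `L/width_px` bases |
| `aggregator` | `"mean"` | per-pixel reduction (see above) |
| `gap_policy` | `"zero"` | value for uncovered columns |
| palettes | 4 greens / 4 blues | light→dark per band, positive/negative hue; interpolated for other band counts |

The shared (`extent_scope = "chart"`) extent is the default because the
multi-sample QC reading — "which track is pale?" — only works when all
tracks share a colour scale; per-track extents are available for
single-track exploration. Values beyond ±V saturate the top band and are
flagged; the renderer marks clipped columns with a 1-px tick.

# Data sources

Three interchangeable backends answer the same region query:

* `bedfile_source()` parses whole files into memory — simplest, exact.
* `build_index()`/`indexed_query()` give seek-and-scan queries on sorted
  files through a sidecar linear index: fixed 16 kb genomic bins map to
  the earliest file offset of a record overlapping the bin, so a query
  seeks to its first bin's offset and scans until the first record
  starting past the region. The sidecar stores the input's size and MD5;
  querying through a stale index is an error rather than a wrong answer.
  16 kb (a power of two) keeps the table small while bounding the scan
  overshoot to roughly one bin of records; it is configurable.
* `serve_bed()`/`http_source()` put the indexed path behind a minimal
  single-threaded RESTful API (`/v1/samples`, `/v1/data/{sample}`), so a
  chart can be built without local data. Record values are serialized
  with shortest-roundtrip precision, which is why a chart rendered from
  the server is byte-identical to one rendered from the files.

The server is deliberately small: no TLS, no auth, no concurrency — a
data-side companion for exploration, not an internet-facing service.

# Rendering and determinism

The renderer emits SVG text with fixed number formatting (three decimals,
trailing zeros trimmed), no timestamps and no generated IDs, so identical
inputs give byte-identical files — the property golden tests and the
file-vs-server comparison rely on. Per column, full bands are drawn at
full track height and the partial band at `fill·h`, bottom band first, so
the darker rectangles overlay the lighter ones and the decode step can
sum heights per column. Runs of identical columns are merged into single
rectangles, a pure optimization with a pixel-identical result. Rounding
heights to three decimals bounds the decode error at well under one
vertical pixel.

# The synthetic coverage generator

`simulate_coverage()` emulates the multi-sample QC scenario the package
is built to display: by default 24 samples over `chr17:1.1M-1.2M`
(100 kb) at mean depth 30, records tiling the region in 100 bp windows
(1000 records per sample — desk scale), two shared dropout intervals (at
30–40% and 60–65% of the region) where depth is scaled to 0.2, and one
sample (the last) whose whole-region depth is scaled to 0.3.

Noise is Gaussian on window means, truncated at zero, with
`noise_sd = sqrt(mean_depth)` by default — the dispersion a
Poisson-distributed per-base depth would show, which keeps simulated
tracks visually similar to real 30x data at this window size. The
generator is *not* a sequencing simulator: no reads, no mapping, no GC
bias, no positional autocorrelation beyond the window structure. Tests
passing on this data therefore demonstrate the plumbing and the
visual encoding — binning, transform, rendering, sources — not
robustness to real-data artifacts like mappability dips or batch
effects.

The dropout multiplier (0.2) and low-sample factor (0.3) are
illustrative round values chosen to be clearly visible yet non-zero;
the parameter-recovery test checks that binned means re-estimate
`mean_depth` within `3·noise_sd/√n_windows` and that the in-dropout to
out-of-dropout depth ratio converges to the multiplier.

# Numerical choices and degenerate inputs

* Boundary rounding is round-half-up (`floor(x + 0.5)`), not banker's
  rounding, for deterministic tiling.
* BED values round-trip exactly: the writer (and the server) emit the
  shortest decimal string that parses back to the same double.
* Malformed BED data lines are errors naming the line number; comment,
  `track`, `browser` and blank lines are skipped and counted. Nothing is
  dropped silently.
* Empty regions, empty files, empty indexes, queries with no overlap and
  all-missing series are all defined, tested cases rather than errors.
* `decompose` is total on finite values plus `NA`; `reconstruct` rejects
  stacks violating the one-partial-band invariant instead of guessing.

# Problem sizes

The checks in `tests/` and `scripts/acceptance.R` run at sizes chosen to
exercise every code path while staying fast on a laptop: 1e5 random
round-trip pairs, 500 fuzzed binning cases on regions up to 10 kb, 200
random queries per source comparison, 64-column charts for decode
fidelity, and the full 24-sample × 1000-window demo scenario. Each is a
scale at which the brute-force oracles are exact and affordable.

# Known limitations

* Missing data and a true zero render identically (blank); only the gap
  policy upstream distinguishes them.
* Chromosome names are compared literally (`chr17` ≠ `17`); no assembly
  liftover.
* BED12 block structure, bigWig/bigBed and binary formats are out of
  scope; gzip BED is read but cannot be indexed (no virtual offsets).
* The server handles one request at a time and offers no authentication;
  bind it to loopback.
* SVG size grows with the number of distinct column stacks; noisy
  many-column charts defeat run merging (a 24×800 chart is a few MB).
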