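# horizonbed

Horizon charts for genomic signal tracks.

## The problem

Sequencing studies routinely need to eyeball one quantitative signal —
read depth above all — across *many* samples at once, e.g. to spot a
library that under-performed or regions that drop out in every sample.
Conventional line/area tracks spend vertical space proportional to the
value range per track, so a 24-sample depth view either towers over the
screen or squashes each track into illegibility.

A horizon chart slices the value range `[-V, +V]` into `n` bands of height
`V/n`, colours band `i` with an increasingly dark ramp (one hue for
positive values, a contrasting hue for negative), mirrors negative values
over the baseline (halving the needed height), and finally collapses all
bands onto the baseline (a further `n`-fold reduction). A track that would
need `2·n·h` pixels of plot area as a two-sided banded chart fits into `h`
pixels, with the darkest visible colour at each x-position still encoding
the value. `horizonbed` adapts this time-series technique to genomic
coordinates: BED/BedGraph intervals in, per-pixel binned values, and a
deterministic multi-track SVG out.

## The core transform

For a binned value `v`, clamp value (extent) `V` and band count `n`, let
`u = V/n` and `s = min(|v|, V)/u`. Band `i` (1-based) gets fill

```
fill_i = clamp(s - (i - 1), 0, 1)
```

so all bands below the value are full, at most one is partial, the rest
are empty. The transform is invertible up to clamping:

```
sign(v) · u · Σ fill_i  =  clamp(v, -V, +V)
```

which is what makes spot-checking rendered pixels against the raw BED
input mechanical: `decode_chart()` reads the rectangles back out of the
SVG and inverts the geometry.

## Worked example

The bundled simulator reproduces a typical multi-sample QC scenario:
24 samples at ~30x depth over a 100 kb window, two intervals where
coverage drops to ~20% in every sample, and one sample whose coverage is
globally low (~30%).

```r
library(horizonbed)

sim <- simulate_coverage(n_samples = 24, seed = 1)
chart <- horizon_chart(sim, region = "chr17:1.1M-1.2M", width_px = 800)
chart
#> <horizon_chart> chr17:1100000-1200000 | 24 track(s), 800 px wide, extent 47.25

glance(chart)
#> # A tibble: 1 × 8
#>   region       n_tracks width_px track_height_px n_bands mode  extent aggregator
#>   <chr>           <int>    <int>           <int>   <int> <chr>  <dbl> <chr>
#> 1 chr17:11000…       24      800              20       4 mirr…   47.2 mean

tidy(chart)
#> # A tibble: 19,200 × 7
#>   sample     col   start     end value displayed clipped
#>   <chr>    <int>   <dbl>   <dbl> <dbl>     <dbl> <lgl>
#> 1 sample01     0 1100000 1100125  27.5      27.5 FALSE
#> 2 sample01     1 1100125 1100250  28.8      28.8 FALSE
#> 3 sample01     2 1100250 1100375  33.4      33.4 FALSE
#> # ℹ 19,197 more rows

write_svg(render_chart(chart), "qc.svg")
```

The extent 47.25 is the largest absolute binned value across all 24
tracks, so every track shares one colour scale; each of the 800 columns
covers 125 bp of the 100 kb region; `displayed` is the value the chart
encodes (the binned value clamped at the extent). In `qc.svg` the two
shared dropout intervals appear as light vertical stripes in every track
and the low sample as a track that is pale end to end — exactly the two
defect classes the chart style is meant to surface. `autoplot(chart)`
gives a quick ggplot2 rendering of the same geometry.

The same pipeline runs from the shell:

```sh
exec/horizonbed simulate --samples 24 --seed 1 --out simdata
exec/horizonbed index simdata/*.bed
exec/horizonbed render --region chr17:1.1M-1.2M --width 800 \
    -o qc.svg simdata/*.bed
exec/horizonbed serve simdata --port 8731   # RESTful region queries
```

Large files are served rather than loaded: `index` writes a sidecar
linear index (16 kb genomic bins → earliest overlapping file offset) and
`serve` exposes `GET /v1/samples` and
`GET /v1/data/{sample}?chrom=&start=&end=`, returning exactly the records
a chart needs. File-backed and server-backed charts are byte-identical.

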