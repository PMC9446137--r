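# woundlabel

Headless, scriptable labeling of wound-tissue photographs in R.

Chronic-wound care tracks healing by the composition of the wound bed:
how much of it is granulation tissue, slough, or necrotic eschar, and
where the wound ends and intact skin begins. Training and evaluating
automatic tissue classifiers requires pixel-level labeled photographs,
and producing those labels by freehand outlining is slow. A faster
protocol is *propose-and-select*: an over-segmentation algorithm
partitions the photograph into small color-coherent segments
(superpixels), and the annotator assigns whole segments to tissue
classes, falling back to a brush and a magic wand for touch-ups.

`woundlabel` implements that protocol as a library with no GUI. Every
interaction is an R function call (or a JSON session script), so
labeling sessions are deterministic, replayable, and testable. The
package provides:

- **imagecore** — `raster_image` (H x W x 3 in [0,1]), PNG/JPEG I/O,
  exact sRGB-to-CIELAB conversion, Gaussian pre-smoothing, gamma
  correction, and half-open 0-based rectangular regions for
  zoom-as-crop.
- **superpixels** — from-scratch implementations of three proposal
  generators: Felzenszwalb's efficient graph-based segmentation, SLIC
  (local 5-D k-means in Lab+xy), and Quickshift (mode seeking on a
  Parzen density estimate), each with fully specified tie-breaking so
  results are bit-reproducible.
- **clustering** — K-means on raw RGB pixels (k-means++ initialization,
  restart selection, seeded), the one proposal type whose "segments"
  may be spatially disconnected, plus `split_connected_components()`.
- **labeling** — sessions, proposal caching, segment selection, brush,
  magic wand (seed-referenced flood fill), zoom regions, gamma, script
  replay, and bit-exact paletted-PNG mask output.
- **evaluation** — confusion matrices, per-class precision/recall/F,
  difference maps, and multi-image reports in both pooled
  (sum-then-score) and macro (score-then-average) aggregations.
- **synthdata** — a seeded generator of synthetic wound scenes
  (irregular star-shaped wound bed on a skin ellipse, slough/necrotic
  blobs, illumination gradient, sensor noise) with exact ground-truth
  masks, standing in for clinical photographs that cannot be shipped.

## Worked example

Generate a synthetic scene, propose superpixels, and score the best
labeling any annotator could reach by pure segment selection:

```r
library(woundlabel)

scene <- generate_scene(scene_params(height = 96, width = 96, seed = 42))
scene$image
#> <raster_image 96 x 96, RGB in [0,1]>

session <- new_session(scene$image)
sp <- propose(session, "slic", slic_params(n_segments = 200))
n_segments(sp)
#> [1] 176

pred <- oracle_select(sp, scene$truth)   # perfect per-segment choices
class_metrics(confusion_matrix(pred, scene$truth))
#> # A tibble: 5 x 4
#>   class       precision recall fscore
#>   <chr>           <dbl>  <dbl>  <dbl>
#> 1 intact_skin     0.955  0.973  0.964
#> 2 granulation     0.923  0.955  0.939
#> 3 slough          0.959  0.892  0.924
#> 4 necrotic        0.935  0.884  0.908
#> 5 background      0.979  0.960  0.969
```

Manual labeling uses the same session:

```r
select_segment(session, sp, segment_id = 0, class_ref = "background")
#> [1] 114
brush(session, center = c(48, 48), radius = 3.5, class_ref = "granulation")
#> [1] 37
magic_wand(session, seed = c(2, 2), tolerance = 0.15, class_ref = "background")
#> [1] 3221

files <- save_pair(session, file.path(tempdir(), "demo"),
                   allow_unlabeled = TRUE)
basename(files)
#> [1] "demo.png"       "demo_label.png"

re <- load_label_map(file.path(tempdir(), "demo_label.png"))
identical(unclass(re), unclass(session$mask))
#> [1] TRUE
```

Label masks are written as paletted PNGs (palette index = class id,
index 0 = unlabeled) and round-trip bit-exactly. The same workflow can
be driven from a JSON script via `run_script()`, or from the command
line:

```sh
Rscript inst/cli/woundlabel.R synth --seed 5 --size 64x64 s5
Rscript inst/cli/woundlabel.R propose --algo slic --n-segments 40 s5.png
Rscript inst/cli/woundlabel.R replay script.json s5.png out
Rscript inst/cli/woundlabel.R eval out_label.png s5_label.png --csv metrics.csv
```

## Design notes

- All pixel coordinates are 0-based `(row, col)`; regions are half-open
  `[top, bottom) x [left, right)`. Zoom is modeled as crop +
  re-segmentation of the crop, with selections mapped back through the
  region offset.
- Every stochastic operation (k-means, scene generation) takes an
  explicit seed and is bit-reproducible; the segmenters are fully
  deterministic with documented tie-breaks.
- `confusion_matrix()` ignores unlabeled pixels by default, so partial
  labelings can be scored; `metrics_report()` always emits both pooled
  and macro aggregations because they genuinely differ when class
  prevalence varies across images.
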