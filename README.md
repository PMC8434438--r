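# depthactions

Action recognition for ambient-assisted-living monitoring from
low-frame-rate **depth-camera** sequences.  The package is aimed at
researchers and engineers building privacy-preserving monitoring systems
for care-home bedrooms: a ceiling-mounted stereo depth camera (2.1 m high,
tilted downward, 320×180 px at 1 fps) records only distances, never RGB,
and the pipeline recognizes what the resident is doing — entering the
room, sitting in the wheelchair, standing, sitting on the bed, lying down,
receiving assistance, or falling.

## Method

The pipeline chains six stages, each exposed as ordinary R functions:

1. **Pre-processing** — depth holes are filled row-wise from the left and
   frames are smoothed with an edge-preserving bilateral filter; the mean
   of the first 30 person-free frames forms the background *B*, with
   unreliable far pixels (> 6 m) removed.
2. **Region extraction** — depth is converted to disparity,
   *d = f·b / Z*, and histogrammed per image row (V-disparity) and column
   (U-disparity).  The floor projects to the slanted *ground correlation
   line*, found by a Hough vote; the bed is the largest remaining
   V-disparity component, bounded by its four extreme points; everything
   else is ignored.  A blob is *on the bed* when > 70 % of its pixels fall
   in the bed region, *on the floor* when > 30 % fall in the floor region.
3. **Foreground and tracking** — a pixel is foreground when
   *B(i,j) − I(i,j) ≥ 0.2 σ(I)*; curtains are removed via their
   U-disparity line; blobs are tracked by gated nearest-centroid
   association (30 px / 5000 px / 0.5 m) and confirmed as a person when
   they move (Σ|ΔD| > 80 over the bounding box) in more than 6 of 10
   consecutive seconds.
4. **Features** — the person silhouette is centred on a 256×176 canvas;
   two action templates accumulate over a recognition window: the depth
   motion appearance *DMA* (pixel-wise running depth minimum) and the
   depth motion history *DMH* (reset to τ on |ΔD| > δ, decaying
   otherwise).  Each template yields a 16×11×9 = **1584**-dimensional HOG
   descriptor; concatenation gives the **3168**-dimensional feature.
   Separately, the floor plane *aX + bY + cZ + d = 0* is fitted to the
   back-projected floor pixels by total least squares, and the person's
   centroid-to-floor distance *D = (aX + bY + cZ + d)/√(a²+b²+c²)*
   measures their height.
5. **Classification and automatic rounding** — a linear multi-class
   classifier scores the fused descriptor.  Long sequences are segmented
   online: a recognition *round* grows frame by frame (min 5 frames) and
   closes as soon as the top class probability reaches Th_prob = 0.30, or
   as *undetermined* after 30 frames.  Closed labels pass height
   overrides: centroid above 1.0 m → *Receiving assistance*; below 0.4 m
   on the floor → *Falling*.
6. **Evaluation** — per-frame accuracy and 8×8 confusion matrices, with
   an optional width-5 block median filter over the label stream.

Because the original care-centre recordings are private, the package
ships a **synthetic scene simulator** (`scene_spec()`, `render_sequence()`)
that ray-casts a parametric bedroom — floor, walls, bed, wheelchair,
optional curtain, and a posed person composite — with per-pixel ground
truth (region masks, person masks, floor plane, per-frame labels), plus
sensor noise and depth holes.  Every stage is validated closed-loop
against this ground truth.

## Worked example

Train on short simulated action sequences, then recognize a 600-frame
synthetic "day" (enter → wheelchair → stand → sit on bed → lie down,
depth noise 0.02 m, 5 % holes; runs in ~2 min):

```r
library(depthactions)

config <- pipeline_config()          # all thresholds, incl. Th_prob = 0.30
spec   <- demo_scene()               # the synthetic bedroom

train  <- build_training_features(spec, demo_training_scripts(8, seed = 2),
                                  config, seed = 100)
model  <- train_classifier(train$features, train$labels, seed = 1)

day    <- render_sequence(spec, demo_day_script(), seed = 11)
result <- recognize_sequence(day$frames, model, config)
result
#> <action_recognition> 600 frames, 109 rounds (108 labelled, 1 undetermined)

evaluate_labels(result$frames$label, day$truth$labels)
#> <action_evaluation> accuracy 94.3% over 598 frames (2 undetermined)
#>
#>      0  1   2  3   4   5 6 7
#>   0 40  0   0  0   0   0 0 0
#>   1 18 20   5  5   0   1 0 0
#>   2  0  0 120  0   0   0 0 0
#>   3  0  0   0 80   0   0 0 0
#>   4  0  5   0  0 135   0 0 0
#>   5  0  0   0  0   0 169 0 0
#>   6  0  0   0  0   0   0 0 0
#>   7  0  0   0  0   0   0 0 0

head(result$rounds, 3)
#> # A tibble: 3 × 5
#>   start   end raw_label label probability
#>   <int> <int>     <int> <int>       <dbl>
#> 1    59    63         2     2       0.711
#> 2    64    68         2     2       0.992
#> 3    69    73         2     2       0.994
```

Rows of the confusion matrix are the true labels, columns the predicted
ones (0 = Outside the room … 7 = Falling).  The resident's five scripted
activities are recognized almost perfectly; the residual errors sit at
the short transitions (label 1) and at the entrance, where the person
rule deliberately waits ten seconds before confirming a person.
`plot_action_timeline(result, day$truth$labels)` draws the frame-by-frame
timeline; `median_filter_labels(result$frames$label, 5)` condenses the
600 labels into 120 block medians.

## Acceptance script

`scripts/acceptance.R` re-runs the whole chain from scratch — renders the
training material, trains the classifier, renders the benchmark day
sequence, recognizes and evaluates it — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/synthetic-scene.R` — parametric room renderer and action scripts
* `R/depth-io.R` — depth-CSV I/O, camera intrinsics, pipeline config
* `R/preprocessing.R` — hole filling, bilateral filter, background model
* `R/roi-extraction.R` — disparity, UV-disparity, floor/bed/curtain
* `R/foreground-tracking.R` — background subtraction, blobs, tracking
* `R/features.R` — silhouettes, DMA/DMH, HOG, floor plane, distances
* `R/recognition.R` — classifier, automatic rounding, evaluation
* `R/pipeline.R` — end-to-end orchestration
* `inst/cli/depthactions.R` — `simulate` / `train` / `recognize` /
  `evaluate` subcommands
* `vignettes/depth-action-recognition.Rmd` — methods and design notes
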