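# fishmetry

Dual-view keypoint morphometry for fish.

Measuring the body dimensions of live fish by hand is slow, stressful for
the animal, and error-prone — and a fish photographed in water rarely
holds a straight pose, so single-image pixel measurements underestimate
curved bodies. `fishmetry` implements an image-based alternative for
aquaculture phenotyping: two orthogonal camera views (lateral "side" and
dorsal "top") are annotated with a fixed keypoint skeleton (10 side-view
and 9 top-view landmarks), a ruler of known length calibrates each view
in cm per pixel, and seven phenotypic traits are computed by planar
vector geometry plus a dual-view 3D length reconstruction that corrects
for horizontal body curvature. The package is aimed at researchers in
fish breeding and morphometrics who have (or want to simulate) such
dual-view keypoint data.

## The method

**Calibration.** For each view, a ruler of true length `L_cm` spanning
`L_px` pixels gives the scale `s = L_cm / L_px` (cm per pixel),
independently per camera.

**3D length reconstruction.** A body segment of true length `|OA|`
appears in the side view with projected length `L` and direction cosine
`cos α` against the horizontal (longitudinal) axis; its top-view
projection has direction cosine `cos β` against the same axis. Then

```
|OA| = sqrt( (L·cosα / cosβ)² + (L·sinα)² )
```

— the horizontal run seen in the side view is stretched by the top-view
inclination, while the vertical rise is already at true length. The
reconstruction never returns less than `L` and reduces to `L` for a
segment parallel to the side-view plane (`cos β = 1`).

**The seven traits** (all in cm): body height (BH), body thickness (BT)
and tail-handle height (THH) are single landmark-pair distances times
the view scale; head length (HL), body length (BL), full length (FL) and
tail-handle width (THW) combine side-view pixel lengths with both views'
direction cosines through the reconstruction above. BL distributes the
side-view mid-body length over the three top-view body segments in
proportion to their apparent lengths; FL adds the shorter caudal-fin
lobe's projection onto the body axis.

**Evaluation.** Automated vs manual measurements are scored per trait by
RMSE, MAE and mean relative error (MRE), plus unweighted averages across
traits. A bundled dataset of 20 channel catfish (*Ictalurus punctatus*,
12–17 cm) measured both ways anchors the regression tests.

The package also provides a synthetic 3D fish generator with known
ground-truth phenotypes (the validation backbone: noiseless synthetic
fish are recovered to better than 1e-6 relative in all traits) and a
compact stacked-hourglass heatmap detector, implemented directly in R,
for localising the keypoints on rasterised views.

## Worked example

```r
library(fishmetry)

# calibrate: 200 px ruler = 20 cm (side), 400 px = 20 cm (top)
scales <- calibrate_views(side_ruler = c(200, 20), top_ruler = c(400, 20))
# c(side = 0.1, top = 0.05) cm per pixel

# a curved synthetic fish with known ground truth, projected and measured
fish <- generate_fish(fish_params(bend_deg = 25))
spec <- project_specimen(fish)
measure_specimen(spec)
#>   specimen_id   FL   BL  BH  BT   HL THH  THW
#> 1   synthetic 14.2 11.3 2.4 2.1 2.72 1.5 1.59

round(fish$truth, 3)    # generator ground truth: identical
#>    FL    BL    BH    BT    HL   THH   THW
#> 14.20 11.30  2.40  2.10  2.72  1.50  1.59

# error statistics of the bundled 20-fish manual-vs-automated dataset
d <- catfish_measurements()
print(evaluate_errors(d$auto, d$manual), digits = 4)
#>             category     MRE    MAE   RMSE
#> 1        Full length 0.03786 0.5167 0.5792
#> 2        Body length 0.02848 0.3040 0.3887
#> 3        Body height 0.08101 0.2066 0.3179
#> 4     Body thickness 0.07550 0.1560 0.1807
#> 5        Head length 0.09588 0.2586 0.3132
#> 6 Tail handle height 0.09603 0.1404 0.1860
#> 7  Tail handle width 0.26421 0.2574 0.3039
#> 8            Average 0.09700 0.2628 0.3242
```

The full length is recovered with a mean relative error under 4%; the
across-trait average is about 9.7%, dominated by the short tail-handle
width, where millimetre-scale annotation error is large relative to a
~1 cm trait.

A command-line tool wrapping these functions (subcommands `calibrate`,
`measure`, `evaluate`, `simulate`, `train`, `detect`) is installed at
`system.file("cli", "fishmetry", package = "fishmetry")`.

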