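# agrocam

Accuracy engineering for tractor-mounted cameras in precision agriculture.

Cameras that locate crop rows and weed patches ahead of a tractor trade off
two families of error sources. First, **geometry**: the extrinsic parameters
— pitch α (from the horizontal; α = 90° is nadir), mounting height h, and
the horizontal distance d to the ground region of interest (ROI) — fix how
many pixels n a 1 × 1 m ground patch occupies, and n is the accuracy
currency of any downstream weed map. Second, **illumination**: an under- or
over-excited sensor and the radial red loss a UV/IR cut filter causes toward
the image corners (vignetting) both corrupt colour-based vegetation
segmentation.

`agrocam` is an R package for users designing such camera rigs or studying
segmentation robustness. It provides:

* a **pinhole arrangement simulator** — project the four ROI corners through
  the camera, take the shoelace area of the resulting trapezoid — swept over
  (α, h, d) grids, plus a bundled table of 125 field-measured pixel counts
  for the same grid and a constrained recommender for choosing an operating
  point;
* an **illumination-control pipeline**: white-panel exposure feedback
  (raise E_t by (1+p) when H = max(R̄, Ḡ, B̄) < aM, lower by (1−p) when
  H > bM, with a = 0.90, b = 0.98, p = 0.20, M = 255), radial vignetting
  correction R_c = (1 + K_r P)·R with K_r = 0.3 and P the
  centre-to-corner-normalised distance pattern, two-class fuzzy C-means
  greenness thresholding on g = G/(R+G+B), and scoring with
  PCC = (TW+TB)/(TW+TB+FW+FB);
* a **synthetic field-scene renderer** (crop rows 0.75 m apart, seeded weed
  blobs, soil, orange reference cardboard, four-colour panel) with a linear
  sensor model and exact ground-truth masks, so the whole pipeline is
  testable without any field data.

## Worked example

```r
library(agrocam)

## which measured arrangement maximises ROI resolution?
t1 <- table1Arrangements()
recommendArrangement(t1)
#>     alpha_deg height_cm distance_m n_pixels
#> 105        50       230          3   129423

## how well does the pinhole simulator track the 125 measurements?
sw <- sweepArrangements()
m <- merge(sw, t1, by = c("alpha_deg", "height_cm", "distance_m"))
cor(m$n_pixels.x, m$n_pixels.y)
#> [1] 0.964

## closed-loop exposure control on a synthetic scene
scene  <- sceneSpec(weed_seed = 1,
                    panel = groundROI(2.3, width_m = 1.2, depth_m = 0.6))
camera <- cameraModel(cameraExtrinsics(20, 220), scaledIntrinsics(320, 240))
ss     <- sceneSensor(scene, camera, sensorSpec(seed = 1))
loop   <- exposureControlLoop(ss$capture, ss$panel_region, exposureState(8000))
tail(loop$trace, 3)
#>   iter exposure_us        H decision
#> 7    7    23887.87 171.2101   raised
#> 8    8    28665.45 205.4514   raised
#> 9    9    34398.54 242.3902     kept
```

The recommender confirms that the closest distance with the steepest pitch
and greatest height gives the peak resolution (129,423 px), while the worst
measured arrangement (α = 30°, h = 210 cm, d = 5 m; 35,648 px) loses 72.5 %
of it. The exposure loop starts from a clearly under-exposed 8 × 10³ µs and
walks the white-panel statistic H into the 229.5–249.9 target band in eight
×1.2 steps.

The full 2 × 2 illumination experiment (`simulateConditionGrid(n_pairs = 10,
seed = 1)`) renders under-exposed/adjusted capture pairs with vignetting and
scores all four processing conditions; its mean PCC cells reproduce the
qualitative field finding — no corrections < vignetting only, and
no corrections < exposure only < both corrections.

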