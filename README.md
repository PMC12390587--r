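# multivein

Contactless **multi-finger vein recognition** and the geometry of the
hand-imaging rig that captures it, in one R package.

Vascular biometrics verify identity from the pattern of subcutaneous veins,
which absorb near-infrared light and appear as dark valleys in NIR images.
A contactless multi-finger platform images all four fingers of a hand at
once, which raises two families of computational problems that this package
addresses for researchers building or evaluating such systems:

* **Acquisition geometry** — thin-lens depth of field
  (`H = f²/(Nc) + f`, near/far limits, Δ), angles of view and first-order
  field of view; clap-coded frame-synchronization recovery for sensors that
  drop trigger pulses; calibrated stereo rectification with the disparity
  law `z = B·f/d` plus block-matching disparity; least-squares photometric
  stereo (`I = L·N`) with flat-field correction.
* **Recognition pipeline** — Otsu + morphological-opening hand masking,
  row-by-row four-finger tracing with anatomical reordering and rotation
  normalization, illumination-correcting vein enhancement,
  **maximum-curvature** binary templates (κ = P″/(1+P′²)^{3/2} maxima of
  valley cross-sections), translation-searched frequency-domain
  cross-correlation matching, FMR/FNMR/HTER evaluation with dev→eval
  threshold transfer (HTER = (FMR+FNMR)/2), and RBF-SVM fusion of
  index/middle/ring scores into hand-level decisions.

Real multi-finger NIR datasets are access-restricted, so the package
includes a seeded **synthetic hand generator** (per-identity vein networks,
per-sample pose/photometric jitter, stereo pairs and photometric-stereo
quadruples with ground truth) that makes every stage testable end to end.

## Worked example

```r
library(multivein)

## Acquisition optics of a f = 4 mm, f/2.5 lens focused at 120 mm
cam <- camera_spec(4, 2.5, 0.004, 3.7, 4.9)
depth_of_field(cam, 120)
#> hyperfocal H = 1604 mm
#> near limit Dn = 112 mm
#> far limit Df = 129 mm
#> DoF = 17.5 mm (s = 120 mm)
round(angles_of_view(cam), 2)
#> horizontal_deg   vertical_deg   diagonal_deg
#>          49.64          62.97          75.01

## One synthetic identity, two presentations, one genuine comparison
id  <- make_identity(7)
r1  <- render_hand(id, render_params(), sample_seed = 1, hand = "RH")
seg <- reorder_fingers(extract_fingers(r1$image), "RH")
seg
#> segmentation_result: 4 finger(s), complete=TRUE [index, middle, ring, little]

mid <- normalize_finger(seg$fingers[[2]])
tpl <- extract_mc(enhance_veins(mid))
tpl
#> vein_template [middle]: 177 x 37, 786 active px (12.0%)

r2   <- render_hand(id, render_params(), sample_seed = 2, hand = "RH")
mid2 <- normalize_finger(reorder_fingers(extract_fingers(r2$image), "RH")$fingers[[2]])
match_templates(tpl, extract_mc(enhance_veins(mid2)))
#> match_score: 0.7863 (overlap 618 at offset dy=0 dx=3)
```

The hand was segmented into four labeled fingers; the middle finger's
maximum-curvature template has 786 active pixels (12% of the crop); matching
it against a second presentation of the same identity scores 0.79 on the
[0, 1] overlap scale (impostor comparisons typically score around 0.4), with
the best alignment found 3 px to the right.

The full benchmark — 20 identities × 2 hands × 5 samples, dev/eval split,
genuine + zero-effort-impostor protocols, threshold at FMR ≤ 0.1%, and
3-finger SVM fusion — runs in about a minute:

```r
res <- run_pipeline(default_config(seed = 0))
res$results$LH_left_850$single$eval   # single-finger eval-set error rates
res$results$LH_left_850$fused$eval    # fused hand-level error rates
```

A thin command-line front end over the same functions ships in
`inst/cli/fvtool` (subcommands `optics`, `simulate`, `sync`, `segment`,
`extract`, `match`, `stereo`, `ps`, `evaluate`, `fuse`, `all`).

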