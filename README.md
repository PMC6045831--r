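# onhrel

Reliability analysis for optic-nerve-head (ONH) morphometry on OCT B-scans.

Swollen optic nerves — papilledema, ischemic neuropathy, drusen — are
monitored quantitatively by delineating two retinal boundaries on a
cross-sectional OCT image: the inner limiting membrane (ILM) at the
vitreoretinal interface and Bruch's membrane (BM) flanking the optic nerve
canal. Because the medial BM margins are shadowed beneath an elevated
nerve, the two BM wings are joined by a straight line, and the **ONH
cross-sectional area** is the area between the ILM and this bridged BM,
truncated to a window of half-width *w* = 2.85 mm about the scan centre
(a 5.7 mm diameter window):

```
A = ∫_{c-w}^{c+w} [ y_BM(x) − y_ILM(x) ] dx      (reported in mm²)
```

with all coordinates converted to micrometres through each image's own
axial/lateral scaling factors. Boundaries are represented as rater-placed
control points interpolated by a shape-preserving (Fritsch–Carlson
monotone piecewise-cubic) curve, the representation used by semi-manual
segmentation tools: the curve passes through every point exactly and never
overshoots between them.

The package is aimed at reading groups who need to know whether such
measurements can be trusted across repeat sessions, raters and devices.
It provides the full agreement toolkit:

- **per-scan segmentation differences** — mean absolute axial difference
  between two delineations of the same scan (ILM, or bridged BM), in μm
  and pixels;
- **95% limits of agreement** (mean ± 1.96 SD) with strict-upper-bound
  outlier flagging;
- **two-way random absolute-agreement ICC**, single-measure ICC(A,1)
  computed from the ANOVA mean squares
  `(MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE))`;
- **Bland–Altman summaries** with 95% CIs on the bias and both agreement
  limits (and a base-graphics plot method);
- a **synthetic phantom study generator** — parametric ONH geometries
  (Gaussian elevation bump over a flat, gapped BM), simulated raters with
  spatially correlated placement noise, and simulated devices with
  distinct pixel grids, axial offsets and scale-calibration errors — so
  the entire chain is testable end to end without clinical data.

## Worked example

```r
library(onhrel)

# a swollen-nerve phantom imaged on a simulated device
spec <- phantom_spec(bump_amplitude = 400, bump_sigma = 800, bm_depth = 1010)
dev  <- device_model("spectral_sim")
sim  <- simulate_device(spec, dev, seed = 1, scan_id = "demo01")
sim$scan
#> <bscan> demo01  (spectral_sim, OD eye, radial protocol)
#>   496 x 512 px, axial 3.87 um/px, lateral 11.3 um/px (1.92 x 5.77 mm)

# one simulated rater segments it; compute the area score
seg <- simulate_rater(sim$apparent_spec, sim$scan, rater_model("R1"), seed = 2)
cross_sectional_area(seg, sim$scan)
#> <area_result> scan demo01 rater R1 session 2: 2.5210 mm^2 (5.7 mm window)
analytic_area(sim$apparent_spec, 2.85)   # ground truth for this phantom
#> [1] 2.568826

# disagreement with a second rater, averaged across the B-scan
seg2 <- simulate_rater(sim$apparent_spec, sim$scan, rater_model("R2"), seed = 3)
segmentation_difference(seg, seg2, "ILM", sim$scan)
#> <difference_pair> scan demo01 ILM (inter_rater): 11.82 um (3.05 px) [R1/2 vs R2/3]

# agreement statistics on an area table (subjects x raters, mm^2)
tab <- cbind(R1 = c(1.72, 2.31, 2.90, 3.25), R2 = c(1.70, 2.33, 2.88, 3.30),
             R3 = c(1.75, 2.28, 2.93, 3.22))
icc_two_way_random(tab)
#> <onh_icc> two-way random, absolute agreement, single measures
#>   ICC = 0.998063  (n = 4 subjects, k = 3 measurers)
bland_altman(tab[, "R1"], tab[, "R2"], id_a = "R1", id_b = "R2")
#> <onh_ba> R1 - R2 (n = 4)
#>   bias -0.0075 mm2  [95% CI -0.0617, 0.0467]
#>   limits of agreement [-0.0742, 0.0592] mm2
```

The measured area sits within rater noise of the phantom's closed-form
truth; the ILM difference (≈12 μm here) reflects two raters each placing
the boundary with ~8 μm spatially correlated error; the ICC near 1 says
between-eye variation dwarfs between-rater variation in the table.

A full factorial study — every phantom eye on every device, segmented by
three raters with a repeat session — is one call each way:

```r
generate_study("study_dir", seed = 1)          # scans + segmentations + manifest
report <- run_study("study_dir/manifest.csv")  # areas, differences, LoA, ICC, BA
print(report); summary(report)
```

`run_study()` stratifies every summary by scan protocol (line vs radial
scans are never pooled, and devices are only compared on radial scans),
honours manifest quality flags for exclusions, and can write
`areas.csv`, `differences.csv`, `loa.csv`, `bland_altman.csv`, `icc.json`
via `out_dir=`. A thin command-line wrapper with `simulate`, `run` and
`validate` subcommands ships in `inst/cli/onhrel.R`.

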