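# beadmetrics

Quantitative image analysis for alginate microbead encapsulation:
morphometry, permeability and pericapsular fibrotic overgrowth (PFO)
scoring, with a seeded synthetic-scene generator so the whole chain is
testable against known ground truth.

## Who this is for

Labs characterizing cell-encapsulation processes (e.g. stem-cell-derived
hepatocyte spheroids in alginate or sulfated-alginate microbeads) need the
same readouts on every batch: the bead size distribution, the number of
encapsulated spheroids per bead, how far FITC-dextran probes of increasing
molecular weight permeate the hydrogel, and — after implantation — what
fraction of each bead's perimeter is covered by fibrotic overgrowth.
`beadmetrics` automates these readouts from calibrated brightfield and
fluorescence images and implements the accompanying statistics.

## What it computes

* **Bead detection** — an edge-based circular Hough transform: Canny-style
  edge map (thresholds relative to the 99th-percentile gradient, so
  detection is exposure-invariant), a (cx, cy, r) accumulator with
  gradient-direction voting, duplicate suppression, and sub-pixel
  refinement by an algebraic circle fit. Each bead reports its diameter in
  µm and a perimeter-support score used to flag malformed beads; small
  satellite beads are flagged by a diameter gate.
* **Morphometry** — batch mean/SD/median diameters and histograms
  (`population_stats`), plus per-bead spheroid counts by Otsu thresholding
  restricted to the bead interior with a watershed split
  (`count_spheroids`).
* **Permeability** — per-bead centre/background intensity ratios and
  two-anchor normalization onto a 0–100 % permeation scale:
  `pct(p) = 100 (r(p) − r(2 MDa)) / (r(4 kDa) − r(2 MDa))`, clamped,
  with the 4 kDa and 2 MDa anchors mapping to exactly 100 % and 0 %.
* **PFO grading** — ray-based perimeter coverage (a ray is covered when its
  annular segment is darker than background mean − 3 SD), five-category
  binning (0 %, 1–25 %, 26–50 %, 51–75 %, 76–100 %) and whole-percent
  cohort summaries.
* **Statistics** — Welch's t-test from raw samples or published summaries
  (t = (m₁−m₂)/√(s₁²/n₁+s₂²/n₂), Welch–Satterthwaite df) and two-sample
  sample-size/power via the noncentral t distribution.
* **Synthetic scenes** — seeded brightfield/fluorescence renderings of
  rimmed beads, spheroids, speckled overgrowth arcs and permeation-graded
  interiors, each with a JSON ground-truth sidecar; and an end-to-end
  `run_pipeline()` with a reproducible manifest.

## Worked example

```r
library(beadmetrics)

# a 12-bead batch drawn at 699 +/- 17 um with ~2 spheroids per bead,
# rendered and re-measured end to end
pop    <- sample_bead_population(12, 699, 17, spheroid_rate = 2, seed = 1)
scenes <- render_scene_set(pop, noise_sd = 0.02, seed = 2)
det    <- do.call(rbind, lapply(scenes, function(s) detect_beads(s$scene)))
population_stats(det)
#> <population_stats> n = 12, diameter 701.3 +/- 17.2 um (median 699.7)
#>   satellites 0.0%, malformed 0.0%

# Welch's test on published assay summaries (albumin, ng/ml, n = 5)
welch_from_summary(66.8, 2.6, 5, 58.9, 3.4, 5)
#> Welch's t-test: t = 4.127, df = 7.486, p = 0.003822 (difference 7.9)

# a priori sample size at Cohen's d = 0.3, alpha 0.05, power 0.8
sample_size_two_sample_t(0.3, 0.05, 0.8)
#> [1] 176

# grade a synthetic implant cohort (coverage drawn in [0.6, 1])
coh <- simulate_pfo_cohort(8, 0.6, 1, seed = 3)
summarize_cohort(coh$records, "unmodified, day 10")
#> <cohort_summary> unmodified, day 10 (n = 8 beads)
#>      0%   1-25%  26-50%  51-75% 76-100%
#>       0       0       0      50      50
```

The batch statistics recover the generating law (701.3 ± 17.2 µm against a
draw from 699 ± 17 µm); the Welch p of 0.0038 sits in the p < 0.01
significance band; the cohort summary shows the percentage of beads in each
coverage grade.

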