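---
title: "Quantifying eve stripe 2 dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying eve stripe 2 dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripeflow)
```

## The problem

During cleavage cycle 14 of the *Drosophila* blastoderm, the pair-rule gene
*even-skipped* (*eve*) resolves from a broad anterior domain into seven sharp
transverse stripes. Stripe 2 is driven by a dedicated enhancer, and variants
of that enhancer — the full ~800 bp element (WT), a truncated 509 bp minimal
element (MSE), and the minimal element in inverted orientation (INV_MSE) —
produce stripes that differ not in their final placement but in their
*dynamics*: how fast the stripe activates relative to stripe 1, how deeply
the anterior border is repressed, which border forms first, and how much the
stripe's position varies from embryo to embryo as it matures.

`stripeflow` implements the measurement chain that turns two-channel
time-lapse movies of such embryos (a nuclear marker plus a fluorescent
reporter) into those phenotypes, together with the Mendelian arithmetic used
to score the viability of the enhancer variants, the interval editing that
defines them, and a synthetic-movie generator with exact ground truth so the
whole chain is testable without any imaging data.

## The synthetic embryo generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline is validated.

**Expression model.** Mean nuclear reporter fluorescence along the
anteroposterior (AP) axis is a constant baseline plus seven Gaussian stripe
components and two localized "fill" components in the 1–2 and 2–3
interstripes:

$$ y(x,t) = b + \sum_{s=1}^{7} A_s(t)\,
   e^{-(x-\mu_s)^2 / 2\sigma_{s}(x,t)^2}
   + F_{12}(t)\, e^{-(x-c_{12})^2/2\sigma_f^2}
   + F_{23}(t)\, e^{-(x-c_{23})^2/2\sigma_f^2}. $$

Three temporal mechanisms shape the pattern:

* **Amplitudes** $A_s(t)$ are piecewise linear on a 3-minute knot grid.
  Stripe 1 is constant at 1 (the within-embryo reference). The presets give
  stripe 2 an increasing (WT, 0.60 → 1.00 over 30–48 min), mildly decreasing
  (MSE, 0.60 → 0.52) or flat (INV_MSE, 0.60) trajectory of
  $A_2/A_1$ — the three qualitative shapes of relative activation.
* **Widths belong to boundaries, not stripes.** The two flanks facing an
  interstripe share one narrowing trajectory (4.8 → 3.8 → 1.8 %EL around a
  per-boundary narrowing time). An interstripe minimum appears when that
  single width falls below the merge threshold set by the stripe spacing, so
  incipient-stripe timing and border-formation order are *emergent*. The 1–2
  and 2–3 boundary times are preset-specific and jittered per embryo
  (sd 2.5 min); all other boundaries narrow at 26 min. Sharing one width per
  boundary has a second purpose: the smoothing spline attenuates peaks in
  proportion to their curvature, and with symmetric flank widths the
  attenuation of stripes 1 and 2 cancels in their peak ratio, keeping the
  relative-activation estimator essentially unbiased.
* **Fills** raise the flanking minima without touching the peaks, and so
  control the border *heights*. The 2–3 fill is a small constant; the 1–2
  fill carries a tail-balancing term (equalising the two valley floors when
  no derepression is present) plus a preset "derepression" trajectory: WT
  decays 0.25 → 0.03 (the anterior border deepens steadily), MSE is 0
  (symmetric borders from the start), INV_MSE decays only to 0.12 (the
  anterior border stays derepressed). Fills ramp in between 28 and 33 min so
  the merged early dome carries no artificial structure.

**Embryo-level variability.** Each embryo draws (i) a positional shift
$z \cdot \sigma_{pos}(t)$ applied to the whole pattern, with $z$ fixed per
embryo so that time-varying $\sigma_{pos}$ produces the preset positional-
variance dynamics (WT shrinking towards ~1 %EL, MSE growing beyond 2 %EL,
INV_MSE constant at 1.5 %EL); (ii) a lognormal factor (sd 0.2) on the
stripe-2 amplitude, the embryo-to-embryo spread of relative activation — the
0.2 scale reproduces cohort error bars of the size seen in real cohorts of
~15 embryos; and (iii) the boundary-time jitters above. Nucleus-level noise
is additive Gaussian with sd 0.06 in stripe-1-peak units; the resulting
spline residuals at the extrema are of the same order as the ~10% error
scale reported for real data.

**Rendering.** `generate_embryo_series()` draws the midsagittal plane as a
512×512, 16-bit frame pair: an ellipsoidal embryo (anterior left, dorsal
up), a cortical monolayer of 100 nuclei (radius 4 px) on the band, interior
yolk autofluorescence, a thin bright vitelline ring just outside the
surface, Gaussian read noise plus square-root (shot-like) pixel noise, and
an optional schedule of cellularization-membrane artifacts. A scheduled
artifact draws a dim line tangential to the embryo surface through the
nucleus: dim enough that the watershed sees two basins (an inner, yolk-side
and an outer, surface-side part), but bright enough that the thresholded
nucleus blob — and with it the topology of the cortical band — stays intact.
Ground truth records every nucleus centre, its AP position, its true
rendered intensity, the split schedule, and dense-grid stripe features of
the noiseless model per frame.

What the generator deliberately does **not** emulate: optics (no PSF,
no z-sectioning), photobleaching, gastrulation movements, nuclear divisions,
or mitotic waves. Passing tests therefore demonstrate correctness of the
measurement chain on data with known truth and realistic artifact structure,
not performance on every failure mode of real microscopy.

## Segmentation

`cortical_mask()` follows the standard morphological route: gray-scale
top-hat (structuring element ≈ 2× nucleus radius) to flatten the smooth yolk
autofluorescence, Otsu thresholding, then erosion followed by morphological
reconstruction, which removes the thin vitelline ring (it does not survive
erosion; nuclei do, and are regrown). A final closing seals the small gaps
between the tightly packed nuclei so the mask's complement separates into an
interior (yolk) and an exterior component. `segment_nuclei()` smooths the
nuclear channel (Gaussian, sd = radius/4 — strong enough to kill shot-noise
maxima, weak enough to preserve the intensity dip across a membrane-split
nucleus) and applies the watershed inside the mask, recording the region
adjacency graph with shared-line lengths (the minimum of the two directed
8-neighbour pixel counts, so a corner contact counts as one pixel) and the
touches-yolk / touches-outside flags.

`fuse_oversegmented()` applies the membrane-split repair rule: two adjacent
regions are one nucleus if their shared watershed line is at least 2 px long
and one region touches the yolk but not the outside while the other touches
the outside and not the yolk. All qualifying pairs are merged by union-find;
the operation is a coarsening of the partition and idempotent, because a
merged region touches both sides and can never qualify again.
`quantify_nuclei()` averages the reporter over each basin's thresholded core
pixels (so inter-nucleus mask pixels do not dilute the mean) and reports
unweighted centroids in 0-based pixel coordinates.

On default synthetic frames the chain recovers 100/100 nuclei with maximum
centroid error ~0.2 px and mean-fluorescence errors within a few percent,
and restores the exact nucleus count on fixtures with up to 10 injected
splits.

## Profiles and stripe features

Profiles are extracted per frame by projecting nucleus centroids onto the
AP axis (anterior pole = 0 %EL) and keeping one side of the midline; the
ventral side is the default analysis substrate as it shows the most mature
pattern. Frame times are registered to the completion of the 13th nuclear
division (±0.5 min).

The feature detector fits a natural cubic smoothing spline minimising

$$ p \sum_i (y_i - f(x_i))^2 + (1-p) \int f''(x)^2\,dx , $$

so that $p = 1$ interpolates and $p = 0$ is the least-squares line; the
operating point is $p = 0.5$. The cost is scale-dependent, so units are
fixed by contract: $x$ in percent egg length, $y$ normalized to the stripe-1
peak. The fit is computed with the Reinsch/Green–Silverman band equations;
extrema come from the exact roots of the piecewise-quadratic $f'$, and both
are verified against dense-grid brute force in the test suite. Samples
sharing a 0.1 %EL bin are averaged before fitting. One caveat is inherited
from the method itself: the roughness-parameter semantics at interior values
follow this specific cost convention, and equivalence with other smoothing
conventions is guaranteed only at $p \in \{0, 1\}$.

Border positions are the unique crossings of $f$ with the mean of two
consecutive extrema (unique because $f$ is strictly monotone between its
extrema); border heights are the value differences between a maximum and its
associated minimum.

**Stripe identity** is assigned at the most mature frame: among maxima
standing clearly above the profile floor, the seven most prominent are
numbered anterior → posterior, using quasi-periodic template numbering so
that a missing stripe (e.g. a weak stripe merged into its neighbour's flank)
leaves a gap instead of shifting every later identity. Identities are then
tracked backwards frame-by-frame by nearest-position matching with a 3 %EL
gate, against reference positions that update as the walk proceeds — so a
one-frame detection dropout does not break the chain. An embryo in which a
stripe cannot be anchored reports NA for that stripe's phenotypes at that
timepoint; cells are dropped, embryos never are.

## Phenotypes and statistics

* **Relative activation** — stripe-2 peak / stripe-1 peak (alternative
  references 3 or 6 are supported by `normalize_profile`).
* **Relative repression** — anterior (2A) / posterior (2P) border-height
  ratio. Ratios above 10 (the configurable plot-exclusion default; large
  ratios arise while a border is first established) are flagged for
  exclusion from time-series plots but retained in all statistics.
* **Incipient stripe** — earliest time at which both flanking interstripe
  minima are detected and maintained at all later timepoints, tolerating one
  missing later frame. Minima are scored inside the 1–2 and 2–3 interstripe
  windows defined by the anchored stripe positions, after pruning spline
  extrema pairs of negligible contrast (< 0.02), so one-sided emergence
  states are representable before the stripe-2 peak individuates.
* **Border order** — which flanking minimum was first detected, requiring
  each minimum to persist to the final frame (it must develop into a mature
  interstripe); same-frame first detection is unresolved.
* **Positional variation** — across-embryo n−1 sample SD of the stripe-2
  peak / border positions per timepoint (never across nuclei), with per-cell
  sample sizes.
* **Group comparison** — two-sided Mann–Whitney–Wilcoxon rank-sum:
  exhaustive enumeration of rank assignments (exact with ties) when
  min(n) ≤ 8, otherwise the normal approximation with tie correction and no
  continuity correction. Two-sided throughout.
* **Temperature** — cohorts at 29C are generated (and can be analysed) on a
  timeline compressed by the ratio of cellularization landmark times,
  38.2 min (25C) / 30.6 min (29C); `scale_developmental_time()` maps 29C
  clock times onto the 25C developmental timeline, and comparisons can be
  run in either absolute or scaled mode — conclusions should state which.
* **Channel concordance** — per-embryo squared Pearson correlation of paired
  per-nucleus values, each channel normalized to its embryo maximum.

## Genetics

`cross_schema()` encodes a two-parent cross as per-chromosome allele pairs.
`cross_expectation()` applies Mendelian segregation per chromosome,
independent assortment across chromosomes, removes balancer-homozygote
classes (CyO/CyO, TM3/TM3 — hard-coded lethals; eve-null rescue classes are
never auto-removed, since their depletion is the measurand) and renormalizes.
Two canned schemas cover the study designs: the standard intercross
(both parents null/CyO; tg/TM3), whose surviving classes include the
homozygous-rescue (1/9), hemizygous-rescue (2/9) and the two control classes
(4/9 + 2/9, a 2:1 ratio), and the hemizygote assay cross (null/CyO mother ×
null/null; tg/tg father), which yields 50% hemizygous rescue.

`rescue_percentage()` scales the combined control-class count by the
Mendelian frequency ratio to get expected rescue-class counts; rescue % is
100·observed/expected with a binomial SD of
$100\sqrt{\hat p(1-\hat p)/n_{exp}}$, $\hat p$ capped to [0, 1] — the
simplest reading of "binomial standard deviations" with n set by the
expectation. Chi-squared ratio and 1:1 sex-ratio tests use the Pearson
statistic with df = classes − 1 and no continuity correction. The
parasegment-3 metric is ps3/(ps3+ps4).

## Constructs

`enhancer_annotation()` holds a sequence, named 1-based inclusive intervals
and binding sites. The shipped reference annotation carries the published
interval lengths — 26 and 18 bp conserved border blocks, 33 bp distal and
211 bp proximal deletion fragments, a 509 bp minimal element (29 bp
extension, free of mapped TFBS, plus the classic 480 bp element) — and the
full footprinted site complement (5 bcd, 3 hb, 6 kr, 3 gt, 1 slp1). Its DNA
sequence is synthetic (seeded random bases) and the in-deletion placement of
kr-1, kr-2, hb-1, hb-2 is synthetic too; real sequence work should load a
user FASTA. One bookkeeping gap is intrinsic to the printed numbers
(798 − 244 = 554 ≠ 509), so the layout keeps every printed length locally
true and adds a 1 bp spacer; no derived fact is hard-coded from it.

`apply_deletions()` removes intervals, shifts all downstream coordinates and
reports fully contained sites as absent; a site straddling a deletion edge
is an error, since the deletions of interest were designed around intact
sites. `invert_segment()` reverse-complements an interval in place (length
preserved, protected border blocks untouchable), remapping site coordinates
end-for-end and flipping strands. `build_variant()` composes these into the
WT / MSE / INV_MSE structures.

## Numerical choices and problem sizes

Degenerate inputs: all-zero frames give empty masks (not errors); empty
masks give empty labelings; monotone profiles have no extrema; undefined
initiation times and unresolved border orders are valid outcomes, not
errors. Ties in identity tracking are broken by distance; a stripe id can be
claimed by at most one peak per frame.

The validation suite runs at desk scale, chosen as the smallest sizes at
which the statistical checks are informative: cohorts of 15 embryos per
genotype on the 24–48 min grid for trajectory recovery (matching real cohort
sizes), 500 single-frame embryos for the positional-SD calibration check
(inside the chi-square 95% CI of the generator's 1.5 %EL), 40 embryos with
widely separated border-narrowing times for classifier accuracy, 100
replicate cohort pairs for rank-sum power, ten 512×512 embryos plus two
split fixtures for segmentation recovery, and 50 random profiles against
10^4-point dense grids for the spline oracles.

## Known limitations

Peak estimates from a smoothing spline are attenuated in proportion to peak
curvature and acquire a small positive bias under noise for weak, flat
stripes; the generator's equal mature widths make the activation *ratio*
nearly unbiased, but absolute peak heights are not. Relative-repression
estimates inherit a geometric bias from the narrower 2–3 interstripe (its
minimum is smoothed upward more than the 1–2 minimum), so measured ratios
drift above truth late in maturation; trajectories remain qualitatively
faithful. Segmentation assumes a laterally mounted embryo with the
midsagittal plane in focus and metadata-supplied orientation; nuclear
tracking across frames and 3-D segmentation are out of scope.
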