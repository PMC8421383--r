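---
title: "Quantifying endolymphatic hydrops: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endolymphatic hydrops: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehquant)
```

## The measurement problem

Endolymphatic hydrops (EH) — pathological distension of the endolymph-filled
membranous labyrinth — is quantified as an *EH ratio*: the endolymphatic
share of an inner-ear fluid space. Two measurement routes exist and need to
agree for imaging-based diagnosis of Ménière's disease to be trustworthy:

* **MRI.** After intravenous gadolinium, three co-registered acquisitions are
  made: magnetic resonance cisternography (MRC; all fluid bright), a
  positive perilymph image (PPI; enhanced perilymph bright, endolymph dark)
  and a positive endolymph image (PEI; reversed contrast). The subtraction
  `HYDROPS = PPI − PEI` makes endolymph negative and perilymph positive;
  multiplying by MRC (`HYDROPS-Mi2`) suppresses non-fluid background while
  preserving the sign. Within a region of interest (ROI) drawn on the
  representative slice, the EH ratio is the count of strictly negative
  pixels over the total ROI pixel count.
* **Histology.** On a representative stained temporal-bone section, the
  endolymphatic spaces are traced and the ratio is an area quotient:
  summed scala-media area over the whole cochlear fluid area; saccule and
  utricle areas over the entire vestibule area; membranous-duct area over
  the canal cross-section.

`ehquant` implements both routes behind the same `eh_measurement` container
(site, side, exact numerator/denominator pixel counts, method), and couples
them to a synthetic phantom generator so that every stage has a known
ground truth.

## The phantom: stylized geometry with exact fractions

The generator's purpose is *validation of area ratios*, not anatomical
realism, so all structures are radial constructs for which the ground-truth
fraction is exact by construction:

* cochlear turns are three concentric annuli around a bony modiolus core;
  the scala media of each turn is an angular sector of its annulus, so a
  sector of angular share $f$ has area share exactly $f$;
* the vestibule is a disk; saccule and utricle are disk sectors, adjacent
  at the direction of the lateral-canal territory so that either organ can
  herniate into it;
* the lateral canal ring is an annulus with an embedded duct band of exact
  area share and an ampullary dilation; standalone canal cross-sections are
  disks with a concentric duct whose radius is $R\sqrt{f}$;
* herniation extends the flagged organ radially into the canal territory by
  20 % of the outer ring radius (configurable), and the territory mask is
  kept one pixel clear of the vestibule boundary so rasterization jitter of
  a non-herniated organ can never trigger a false call.

**Rasterization.** Labels are evaluated on a 4× supersampled grid and each
pixel takes the majority label of its 16 subsamples, which keeps the area
bias of every region below about one boundary-pixel row; acceptance-level
tolerances are in the third decimal at 128² in-plane grids. Ties in the
majority vote break deterministically toward the lower label code; region
boundaries are deliberately placed at generic angles and sub-pixel center
offsets, because an edge lying exactly along a pixel-center row would turn
every boundary pixel into an exact tie and the deterministic break into a
systematic one-row area bias.

**Signals and noise.** Each contrast assigns a per-compartment mean (bone,
perilymph, endolymph) and adds independent zero-mean Gaussian noise. The
constructor enforces the contrast logic (perilymph positive and endolymph
negative after PPI − PEI, fluid brighter than bone on MRC); everything else
about pulse-sequence physics is out of scope. The default noise SD of 20 is
5 % of the 400-unit compartment contrast: clearly visible grain, negligible
sign-flip probability. The pipeline tolerates at least 10 % (a documented,
regression-tested bound of 0.05 on the measured ratio). Gaussian rather
than Rician noise is used because only the sign of a subtraction is ever
consumed.

**Through-plane layout** (slice 1 = most inferior; 10 slices by default,
1 mm apart): the vestibule/ring stack spans five slices on which the ring's
visible arc grows 200° → 250° → 360°, so the vestibular slice rule has a
unique answer that is *not* simply "any slice"; the cochlea spans five
slices with the modiolus extent peaking in the middle, so the cochlear
tie-break is exercised. Voxels default to 0.5 × 0.5 × 1.0 mm.

## Cohort simulation

`simulate_cohort()` draws per-ear true fractions from group distributions
whose defaults are the published group statistics (`eh_group_params()`):
cochlea 0.314 (SD 0.118) affected / 0.064 (0.022) control; combined
vestibule 0.757 (0.205) / 0.289 (0.062); saccule 0.513 (0.214) and utricle
0.242 (0.124) on the affected side; ampullary canal fractions 0.565 / 0.511
/ 0.518 (anterior / lateral / posterior, affected) and 0.515 / 0.456 /
0.491 (unaffected); MRI-side cochlea 0.372 (0.164) and vestibule 0.533
(0.250) at n = 72. Published values exist only for the ampullary canal
regions; the non-ampullary regions were reported as indistinguishable, so
the same parameters are reused. The healthy-control canal parameters are
not published either; the unaffected-side values stand in as the closest
non-diseased reference. Herniation is a per-ear categorical draw
(saccular 15/54, utricular 9/54 among affected ears; absent in controls).

Draws are normal, *clipped* (winsorized) to (0.001, 0.999) — a fraction
must stay inside the open unit interval, and at the published parameters
the clip shifts means by at most ~0.012 (the largest effect is on the
combined vestibular draw, whose upper tail crosses 1).

**Saccule and utricle are drawn jointly, anticorrelated.** The two organs
partition the fixed vestibular space, so `saccule + utricle < 1` is a hard
geometric constraint. At the published SDs, *independent* draws violate it
about 16 % of the time, and redrawing violators would depress the saccular
sample mean from 0.513 to about 0.46 — the generator would no longer emulate
the population it claims to. The organs' residual variation is therefore
modelled as competition for space: a bivariate normal with latent
correlation −0.8 (exposed as `cohort_spec(organ_correlation = )`), each
marginal keeping the published mean and SD. Violations drop to ~4 % and the
redraw rule (pairs violating the constraint are redrawn, at most 100
rounds, then an error) leaves the simulated marginals at 0.497 / 0.247.
Groups for which only a combined vestibular distribution is published are
drawn on the combined scale and split between the organs at the published
contribution ratio 0.513 : 0.242.

## ROI selection rules

* **Cochlea:** among slices showing all three turns, the slice with the
  largest modiolus pixel count wins; ties break toward the more inferior
  slice. "Greatest height" of the modiolus is operationalized as in-plane
  pixel count because it is reproducible and monotone in extent on an
  axial slice. The cochlear ROI is the fluid of the three turns — the
  contour follows the fluid-bright signal on cisternography, so the bony
  modiolus core contributes pixels to neither numerator nor denominator.
* **Vestibule:** the lowest slice on which the lateral canal ring is
  visible for *strictly more than* 240° of arc; the ROI is the vestibule
  label minus any ampulla pixels. Arc visibility is measured by binning
  ring-pixel angles around the centroid of the full 3D ring projected
  in-plane (stable even when single slices show partial arcs). Bins are 1°
  by default in `arc_coverage()`; `select_vestibule_slice()` widens them
  adaptively to about twice the angle one pixel subtends at the ring's
  median radius, because on a coarse grid a full ring populates only
  ~2πr of the 360 one-degree bins and fixed-width bins would understate
  visibility (the criterion itself only needs coarse angular resolution).
  A single representative slice is measured, not an average over slices.

## Measurement conventions

* Counting is on raw signed HYDROPS-Mi2 values; the display window
  (level 400, width 1000, `apply_window()`) exists for figure export only,
  since windowing destroys sign.
* The threshold is strictly negative: zero-valued pixels (background, or
  zero cisternography signal) count as non-endolymph. The denominator is
  every ROI pixel.
* Compositions always run in floating point, so integer input images can
  never wrap under subtraction.
* Canal ratios are reported as duct / cross-section (the endolymph share),
  the orientation that lies in [0, 1] and matches the published canal
  values (0.456–0.565).
* Organ areas include herniated pixels outside the vestibule boundary, as
  a traced organ contour would; the combined vestibular ratio equals
  saccular + utricular exactly because the three share one denominator.
* Ratios are kept at full precision; display rounds to 3 decimals.

## Statistics

`compare_groups()` mirrors the study's workflow: Shapiro–Wilk per group at
α = 0.05, then a two-sided Welch t-test if both groups are compatible with
normality, otherwise a two-sided Mann–Whitney test. Welch rather than
Student is used because group SDs differ up to five-fold; the branch taken
is always recorded. A zero-variance group has no Shapiro–Wilk statistic and
is routed to the rank test. No multiple-testing correction is applied (raw
p-values are reported), and all tests are two-sided.

Two cautions from direct simulation at the published moments: the
histology-vs-MRI cochlear comparison (0.372 ± 0.164, n = 72 vs
0.314 ± 0.118, n = 54) has about a 2.3-σ standardized difference and is
*significant in roughly two-thirds of replicates* — the original
non-significant finding reflects the real paired data, not normal draws at
the printed moments. The same holds for the ampullary anterior-canal
affected-vs-unaffected comparison. The package's tests therefore assert
only what replication at the printed moments supports (the
histology-vs-MRI contrast is orders of magnitude weaker than
case-control), not the original significance calls for those two
comparisons.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
rasterized areas against shoelace polygon areas of the analytic boundaries;
negative-pixel counts against an explicit per-pixel double loop; slice
selection against brute-force per-slice label scans; arc coverage against
analytic arcs; sampling against closed-form clipped-normal expectations.
Study-level checks simulate cohorts at the published group sizes (54
affected and 17 control histology ears, 72 MRI ears) on 128² × 10 grids —
large enough that rasterization bias (≲ 0.006 on a ratio) is well inside
one standard error of any cohort mean, and small enough that a full
replicate suite runs in a few minutes on a laptop core. Because a single
cohort mean at n = 54 has a Monte-Carlo SE of ~0.016–0.03, the suite
averages three replicate cohorts per target before comparing against the
±2 SE recovery band; the acceptance script reports honest single-run values.

## What the phantom does not show

Passing these tests demonstrates that the *measurement chain* is unbiased
and rule-faithful on geometry whose ground truth is known. It does not
demonstrate robustness to the things real data add: partial-volume effects
beyond supersampled rasterization, registration error between contrasts
(grids are assumed aligned, as on a scanner console), intensity
inhomogeneity and Rician noise statistics, anatomical variation of the
labyrinth, manual-contour variability between raters, or section-plane
obliquity in histology. The cohort counts of the source populations are
also internally inconsistent in the original report (e.g. 37 cases
described as 72 ears, 54 affected ears, an abstract herniation percentage
matching neither 15/54 nor 15/72); the generator takes group sizes as
explicit configuration and does not attempt to reconcile them.
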