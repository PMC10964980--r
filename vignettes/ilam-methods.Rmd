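---
title: "Isochronal late activation mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isochronal late activation mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilamr)
```

## The problem

After surgical repair of tetralogy of Fallot, ventricular tachycardia runs
through *anatomical isthmuses* (AIs): strips of surviving myocardium bounded
by non-conducting structures — the tricuspid and pulmonary annuli, the VSD
patch, the RV incision or transannular patch, and surgical scar. Four
classical corridors are distinguished by their bounding pair: tricuspid
annulus to incision (AI1), incision to pulmonary annulus (AI2), VSD patch to
pulmonary annulus (AI3) and VSD patch to tricuspid annulus (AI4). Nearly
every patient has at least one AI, but only *slow-conducting* isthmuses
(SC-AI, conduction velocity below 0.5 m/s) sustain re-entry. The package
implements the automated workflow that finds them from a high-density
electroanatomical map acquired in sinus rhythm, without inducing the
arrhythmia.

## The mapping model

**Local activation time (LAT).** Each mapping site records several orthogonal
bipolar electrograms from a grid catheter (3 mm electrode spacing); the
bipole with the largest peak-to-peak amplitude is kept and its amplitude
becomes the site voltage (below 1.5 mV is abnormal). LAT is annotated at the
*offset of the last electrogram deflection* — in scarred myocardium the
terminal, late component reflects the local slow wavefront rather than
far-field ventricular activation.

**Eight isochrones.** The mapped LAT range `[LATmin, LATmax]` is divided into
eight equal-duration bins; total activation time is `LATmax - LATmin`. Since
each bin covers the same time span, the *spatial* width of an isochrone band
is proportional to local conduction velocity:

$$ w \approx \frac{v \, T}{8} $$

with `T` the total activation time. Slow regions therefore show *isochronal
crowding*: many isochrones packed into little space.

**Deceleration zones (DZ).** A vertex is crowded when more than three
distinct isochrone indices occur within a 1 cm geodesic radius ("1 cm" read
literally as a radius of 10 mm). DZs are connected components of crowded
vertices, with components below 10 mm² discarded as sampling speckle. A zone
is flagged as *extreme slowing* only when crowding is denser (peak count at
least 6) **and** the majority of its mapping sites show fractionated
electrograms — both conditions are required.

**Isthmus grading.** Each corridor's conduction time is the difference of
endpoint LATs, each endpoint taken as the median over a 3 mm cap (robust to
single-point annotation error); CV is the geodesic axis length divided by
conduction time (mm/ms, numerically m/s), rounded only at the report layer.
An isthmus is SC when CV is strictly below 0.5 m/s. Isochrones/cm along the
axis is counted continuously — LAT span along the axis divided by the bin
width, plus one — which is the continuum form of the width law (`8/(vT)` per
unit length). Integer counting was considered and rejected: on an 18 mm axis
it collapses the measure into three or four tied levels, drowning the
monotone relation between crowding and CV in quantization noise, while the
continuous count reproduces the same rounded integers at the display layer.

**Lines of block and collisions.** A line of conduction block is a chain of
close vertex pairs whose LAT difference exceeds one bin width, supported by a
split potential nearby (isoelectric gap strictly over 20 ms), and is
confirmed when the LAT gradient has opposite signs on its two sides.
Wave-front collisions (local LAT maxima with two opposing approach
directions) are reported as warnings rather than auto-rejecting zones, since
mapping during pacing is the clinical way to avoid them.

## The synthetic generator

No patient maps are distributed, so the package ships a seeded generator
that builds the study conditions from scratch:

* **Geometry.** A developable "opened RV" sheet (flat triangulated grid,
  1 mm spacing) carries rectangular or disc-shaped non-conducting structures;
  a cylindrical variant exercises wrap-around activation. All quantities of
  interest are surface-intrinsic, so a full 3-D ventricle adds nothing.
* **Activation.** First-arrival times by Dijkstra on the mesh edge graph,
  with edge traversal time = length / harmonic mean of the endpoint CVs — a
  first-order eikonal approximation. The metric graph augments the
  triangulation with second diagonals and order-2 links (16-neighbourhood),
  keeping the geodesic anisotropy of the grid below 3%.
* **Electrograms.** Each wavefront passage contributes a compact biphasic
  wavelet whose support ends exactly at the local activation time, ending in
  a sharp terminal stroke so that threshold-based offset annotation recovers
  the planted LAT to within one sample by construction. Sites with local CV
  below 0.25 m/s receive a presystolic train of low-amplitude wavelets
  (continuous fractionated activity); sites reaching two activation clusters
  separated by more than 20 ms across a severed line record both components
  (split potential); sites over scar or patch record noise only and come
  back unusable. White noise (default SD 0.02 mV) models acquisition noise.
* **Corridor study unit.** The standard scenario is a 112 x 30 mm sheet with
  two blocks leaving one corridor of length 18 mm (the worked clinical
  example) and width 11 mm (the reported median AI3 width), background CV
  1.0 m/s, paced from the far edge. The sheet length was chosen *once*, from
  the width law above, so that the corridor's isochrone width crosses the
  1 cm crowding radius near 0.5 m/s — the detector's boundary lands at the
  SC threshold, mirroring the deliberately restrictive DZ definition used
  clinically to target SC-AI rather than all conduction slowing.
* **Cohort.** 27 corridors (the size of the clinical isthmus cohort) with
  planted CVs uniform on 0.1–1.5 m/s, sampled at 20 sites/cm², annotated
  noiselessly for the recovery benchmark. One root seed drives named
  substreams for every stochastic draw, so a fixed seed reproduces the
  cohort bit for bit.

### What the generator does *not* emulate

Fibre anisotropy, transmural activation, far-field components, catheter
contact artefacts, respiratory/cardiac gating, and the geometric diversity
of real repaired anatomy. Passing the recovery benchmarks therefore shows
that the *pipeline* is correct and well-calibrated under controlled
conditions — not that it would reach the same accuracy on clinical maps.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `voltage_abnormal_mV` | 1.5 | mV | abnormal bipolar voltage (strict `<`) |
| `dense_scar_mV` | 0.5 | mV | dense-scar surrogate cutoff (strict `<`) |
| `split_gap_ms` | 20 | ms | isoelectric gap flagging a split potential (strict `>`) |
| `dz_radius_mm` | 10 | mm | crowding radius ("1 cm") |
| `dz_min_isochrones` | 4 | – | distinct isochrones required (strictly `> 3`) |
| `min_zone_area_mm2` | 10 | mm² | speckle suppression for DZ components |
| SC threshold | 0.5 | m/s | slow conduction (strict `<`) |
| `noise_floor_mV` / `deflection_min_slope` | 0.05 / 0.1 | mV, mV/ms | deflection significance, calibrated to the synthetic wavelets |
| `max_distance` / `fill_radius` | 5 / 5 | mm | point projection cutoff / IDW interpolation radius |

The dense-scar voltage cutoff replaces pacing non-capture confirmation
(10 mA / 2 ms), which an offline pipeline cannot perform; 0.5 mV is the
standard convention. Deflection significance defaults are calibrated to the
synthetic signal model only — vendor thresholds are not public.

## Numerical choices

* Binning is over the map's own activation span, not a fixed window; the
  last bin is right-closed (the latest vertex takes index 7), all others
  right-open.
* Exact bipole-amplitude ties resolve to the lowest bipole index.
* Interpolation is inverse-distance-weighted (power 2) over geodesic
  distances, exact at point-bearing vertices; vertices with no point within
  the fill radius stay unmapped rather than being extrapolated.
* Corridor width uses the minimal boundary-to-boundary distance with a
  half-spacing correction on each side (the continuum boundary lies half an
  edge beyond the outermost labelled vertex).
* Degenerate inputs error early and explicitly: zero conduction time, a
  constant LAT field, an unmapped isthmus endpoint, a sub-5 mm axis.
* Manual offline re-annotation is replaced by deterministic re-annotation
  under a stricter configuration; there is no interactive editing.

## Problem sizes

The default corridor map has ~3,500 vertices; the cohort runs 27 full
pipelines (activation, ~700 electrogram sites, interpolation, crowding
counts) in a few minutes on one core. These sizes were chosen so that the
mesh spacing (1 mm) sits well below every length scale of interest (corridor
width 11 mm, crowding radius 10 mm) while the full validation remains cheap
to re-run.

## Known limitations

* The DZ detector's boundary is physical, not sharp: corridors planted just
  above 0.5 m/s (up to roughly 0.58) can produce a marginal fourth
  isochrone within the radius and be flagged. Sensitivity for true SC is
  robust; specificity loses a corridor on unlucky draws near the threshold.
  Clinical isthmus CVs cluster far from the threshold on both sides, which
  is why both here and clinically the discrimination looks cleaner than the
  worst case.
* With annotation noise, endpoint LAT medians shift by a few ms; the
  recovery tests show 95% of sites annotate within 2 ms at 0.02 mV noise,
  which degrades CV estimates of fast corridors (short conduction times)
  first — slow-corridor classification is the robust quantity.
* The F-score computed from the published confusion counts (10/11
  sensitivity, 16/16 specificity) is 20/21 = 0.952; the corresponding
  published headline value is 0.94. The package reports the full-precision
  recomputation and treats 0.94 as a lower bound.
* The eikonal approximation ignores wavefront curvature and source size;
  with 1 mm edges its error is dominated by the residual 2.7% grid metric
  anisotropy.
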