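---
title: "Scoring in vivo motility screens with the Compactness Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring in vivo motility screens with the Compactness Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compactscreen)
library(dplyr)
```

## The measurement problem

In avian-embryo xenograft screens, cancer cells injected intravenously
extravasate in the chorioallantoic membrane (CAM) and grow into metastatic
colonies of roughly 50–100 cells. Motile cells wander away from the
extravasation point and produce diffuse, spread-out colonies; cells whose
in vivo motility is impaired — for instance by an shRNA knocking down a
motility gene — produce tightly packed, compact colonies. Colony
morphology is therefore a readout of in vivo motility, and a pooled shRNA
screen can be scored by asking: *how compact are the colonies formed by
each clone, relative to colonies formed by scramble-shRNA control cells?*

`compactscreen` implements that scoring pipeline end to end: per-colony
morphology attributes from fluorescence images, per-clone Z-scores and the
composite Compactness Index (C.I.), hit calling with one-way ANOVA and
Fisher's LSD, deconvolution of shRNA identities from hairpin amplicon
reads, and the downstream motility metrics (cell-track statistics,
acute-angle distributions, Alu-qPCR burden quantification). A seeded
synthetic-data layer generates colony images, hairpin reads, tracks and Ct
tables with known ground truth, so every stage is testable without
external data.

## The colony model and its three attributes

Each colony image is scored on three complementary attributes, chosen so
that differences in proliferation (colony size per se) do not masquerade
as differences in motility:

* **Cell distribution (`sigma_px`)** — the image is background-corrected,
  masked, and translated so the intensity-weighted mask centroid sits at
  the image center. Eighteen copies rotated 20° apart (a full 360° sweep)
  are each collapsed to a row-averaged intensity line plot, the eighteen
  profiles are averaged, and a Gaussian
  $a\,e^{-(x-\mu)^2/2\sigma^2} + c$ is fitted by nonlinear least squares.
  The fitted $\sigma$, in pixels, measures how far cells sit from the
  colony centroid.
* **Colony area (`hull_area_px`)** — the pixel count of the convex hull
  of the cell mask. Hull membership is decided on pixel centers with
  exact integer arithmetic; a single pixel has area 1 and collinear masks
  count the lattice points on the segment.
* **Colony density (`density`)** — the fraction of hull pixels occupied
  by cells, in $(0, 1]$.

Attributes are combined per clone as Z-scores against the control
reference (sample mean and $n-1$ SD over at least ten control colonies):

$$Z(\text{attribute}) =
  \frac{\text{clone mean} - \text{control mean}}{\text{control SD}},
\qquad
\text{C.I.} = Z(\text{density}) - Z(\text{distribution}) - Z(\text{area}).$$

Compact colonies are denser, tighter and smaller, so all three terms push
their C.I. positive; dispersed, motile colonies score negative. A clone
scored against a reference built from its own colonies has C.I. exactly 0,
which is the pipeline's self-consistency check.

```{r self-score}
set <- simulate_colony_set(control_sigma = 40, clone_sigma = 40,
                           n_colonies = 10, seed = 101)
feats <- score_colonies(filter(set, role == "control"))
feats$clone_id <- "scramble"
score_clones(feats, control = "scramble") |>
  select(clone_id, z_density, z_distribution, z_area, ci)
```

## Preprocessing choices

**Background subtraction.** The global background level is estimated as
the mode of the nonzero-support intensity histogram (exact most-frequent
level for quantized images, the fullest of 256 bins otherwise) and
subtracted with clipping at zero. Zero pixels are excluded from the
estimate so that black padding introduced by cropping or translation
cannot drag it down; when zeros are the majority of the frame the image
is mostly empty and the background is taken to be zero. Without this
rule, a translated copy of a colony acquires a spurious ~tens-of-units
residual baseline and its fitted $\sigma$ can shift by ~20%; with it,
integer translation changes $\sigma$ by well under 1%.

**Illumination correction.** Uneven illumination is removed with a
morphological white top-hat using a disk structuring element of radius 10
pixels (the element a practitioner would use for cells a few pixels
across). The top-hat output is the intensity field used for the radial
profile.

**Cell mask.** Otsu's threshold is applied to the background-subtracted
*pre-top-hat* image (the "detection" field), not to the top-hat output.
This is a deliberate choice: a white top-hat suppresses bright structures
larger than its element, so a densely fused compact colony — precisely
the phenotype the screen selects for — is hollowed out to a rim if
thresholded after top-hat. Empirically that inverts the density
attribute (mean density 0.44 at dispersion 20 px falling to 0.25 at 5 px)
and destroys the monotonicity of the C.I.; thresholding the detection
image keeps solid cores solid (density 0.46 rising to 0.93 over the same
range) while the top-hat still serves the profile. `binarize_colony(on =
"tophat")` restores the alternative, and a fixed threshold is available
for calibrated setups.

**Rotation and interpolation.** Rotations are performed about the pixel
center of the image center with bilinear interpolation and zero fill.
The 18 × 20° grid is the procedure's fixed design; note it is not
symmetric under a 90° rotation of the *input* (90 is not a multiple of
20), so hard-edged anisotropic objects can show percent-level profile
differences between a colony and its rotated copy. Smooth objects —
which rotation-averaged colony images are — agree to well under 1%, and
the fitted $\sigma$ of simulated colonies changes by under 2% under
lossless 90° rotation.

**Degenerate inputs.** All-zero images, empty masks, flat profiles and
diverging fits raise stage-tagged errors (`"empty image"`,
`"no cells detected"`, `"unfittable profile"`); colonies touching the
frame are scored but flagged `on_border`, since their hull and $\sigma$
are then lower bounds.

## Hit calling

Per-colony C.I. values (each colony Z-scored individually against the
control reference) feed a one-way ANOVA across clones; each clone is then
compared to the control with Fisher's LSD using the pooled within-group
variance. The returned per-clone p-values are the unadjusted LSD
p-values; the `significant` flag additionally gates them on the omnibus
ANOVA at $\alpha = 0.05$ (the classical *protected* LSD, which is
strictly more conservative). With two groups the LSD comparison is
algebraically the pooled-variance t-test. Hits are clones with
$p \le 0.05$, C.I. $\ge 5$, and (by default) a single integrated shRNA,
ranked by C.I. with ties broken by clone id.

Two Poisson design calculators accompany the screen: the probability that
a transduced cell carries exactly one integration,
$p_1 = \lambda e^{-\lambda} / (1 - e^{-\lambda}) \approx 0.90$ at the
screening MOI of 0.2, and the embryo count needed for library coverage.
The coverage model is exposed in two interpretations — per-shRNA
confidence (default) and whole-library joint confidence — because the
published screen's printed numbers cannot be reproduced from a single
simple Poisson reading; neither mode is privileged.

## shRNA deconvolution

Reads of the amplified hairpin insert are validated with a stringent
substitution-only (Hamming) filter:

1. **Flank anchoring** — best placement of the 5' then the 3' vector
   flank, in the read and its reverse complement; at most 2 mismatches
   per flank, ties and conflicts are ambiguous and fail.
2. **Loop check** — the construct loop located by best placement inside
   the insert (ties broken toward balanced arms); zero mismatches
   tolerated by default.
3. **Stem check** — the loop-proximal arms must be exact reverse
   complements (zero mismatches by default; G:U wobble is not accepted,
   as the reads are DNA).
4. **Library match** — the extracted sense arm matched to the library by
   minimum Hamming distance (≤ 2), requiring a unique best record.

All four tolerances are exposed as arguments. Clones are classified from
ranked pass-read counts: fewer than 50 pass reads is `"none"`, a dominant
shRNA holding ≥ 95% of pass reads is `"single"`, anything else
`"multiple"`. The dominance threshold is a package choice (the outcome
rule is not published); the simple dominant-fraction rule avoids an
unclassifiable gap between the single and multiple conditions and
reproduces 60/40 mixtures as `"multiple"` and 99/1 as `"single"` in
≥ 99/100 seeded replicates at 1000 reads per clone and 1% per-base error.

Indel-containing reads are not realigned; with amplicon reads of a fixed
construct this is rare, and such reads fail the flank or stem contract
rather than being silently mis-assigned.

## Motility metrics

Track **velocity** is total path length over total time (identical to the
mean per-step speed at the fixed 15-minute sampling interval the
defaults emulate) and **displacement rate** (productive migration) is the
net start-to-end distance over total time; displacement rate never
exceeds velocity, with equality only for straight monotone motion.
Protrusion and fiber angles are reduced to their acute equivalent
$\min(a \bmod 180°, 180° - a \bmod 180°)$ and binned in 10° half-open
bins over $[0°, 90°]$, the top bin closed.

Alu-qPCR burden uses a least-squares standard curve
$C_t = \text{slope} \cdot \log_{10}(\text{cells}) + \text{intercept}$
(slope $-1/\log_{10} 2 \approx -3.32$ at 100% efficiency). Sample Cts are
first corrected by $\Delta C_t$ of their normalizer (mouse GAPDH in the
assay this models) against the run mean — the published assay states
normalization "for tissue input" without a formula, so the package uses
this convention and documents the round-trip identity (every standard's
cell count recovered within 1%) as the test surface rather than any
animal-specific numbers. Cts outside the dilution range are flagged as
extrapolation. Relative burden is the group mean divided by the control
group mean, × 100.

## What the generators emulate — and what they do not

* **Colony images** (`simulate_colony`, `simulate_colony_set`): cell
  centers i.i.d. isotropic bivariate normal about the image center
  (dispersion SD in pixels is the motility surrogate), cells as
  uniform-intensity disks, background = level + linear ramp + Gaussian
  noise clipped at zero. Defaults: 75 ± 25% cells per colony (the 50–100
  regime), 256 px frames, 5 px cell radius, intensity 1000 over
  background 100, ramp 0.2 units/px, noise SD 20. Pixel scale is
  nominal — no µm calibration is implied, and all three attributes are
  scale-relative once a control reference is fixed. Not emulated: point
  spread, cell–cell exclusion, z-stacks, vasculature or collagen
  channels. Passing tests therefore demonstrate the *operators*, not
  robustness to optical artifacts of real stereoscope images.
* **Hairpin reads** (`hairpin_library`, `simulate_hairpin_reads`):
  `flank5 + sense + loop + revcomp(sense) + flank3` with the public
  miR-30 scaffold context as a synthetic stand-in (the commercial
  library's exact flanks are proprietary; they are plain required inputs
  to the matching layer), substitution errors at a per-base rate, and
  planted single-base loop or single-arm stem defects with a truth
  table. No indels or quality-dependent errors by default.
* **Tracks** (`simulate_tracks`): persistent random walks, constant step
  speed, heading kept with probability `persistence`; defaults (20
  tracks, 15-min interval, ~7 h) match the intravital time-lapse design.
  Drift and tracking errors are out of scope — tracks are assumed
  registered.
* **qPCR tables** (`simulate_qpcr_table`): an idealized dilution series
  plus samples and normalizers generated from the same line, optionally
  with noise and per-sample input shifts.

## Problem sizes and numerical notes

The test suite and the acceptance script run entirely on generated data
at deliberately modest sizes: 10 colonies per clone at 256² px (the
minimum the scoring design calls for), dispersion ladders over
{40, 20, 10, 5} px against a 40 px control, 1000-replicate null
simulations for the LSD calibration, 100 seeded deconvolution replicates
at 1000 reads per clone, and 200-track motility comparisons. The Gaussian
fit is Levenberg–Marquardt with analytic-free bounds ($\sigma > 0$),
initialized from the profile (amplitude = max, center = argmax, $\sigma$
= HWHM/1.177, offset = min). Convex-hull membership uses exact integer
cross products, so hull areas are reproducible to the pixel. All
generators are seeded and bit-reproducible, including written TIFF/FASTQ
fixtures.

## Known limitations

* One colony per image is assumed; there is no colony detection or
  segmentation of crowded fields.
* The C.I. is relative to the control reference by construction; absolute
  values depend on the imaging scale and are not comparable across
  setups without a shared control.
* Manual annotations of the original assay (invasive cells per field,
  protrusions per cell, collagen-fiber engagement, vessel contact) are
  supported only as generic group statistics, not computed from images.
* BLAST-style annotation against external sequence databases is out of
  scope; gene annotation comes from the library table.
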