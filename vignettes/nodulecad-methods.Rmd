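---
title: "Models and methods behind nodulecad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nodulecad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nodulecad)
```

`nodulecad` detects stiff spherical nodules buried in a soft agar block by
combining two per-point measurements taken on a 2 mm indentation grid:
an indentation stiffness and a pulse-echo reflectometric amplitude index.
This vignette documents the underlying models, the parameters that matter,
the simulator that stands in for the mechatronic scanning platform, and
the choices made where the design was genuinely open.

## The phantom model

A phantom is a rectangular block — reference size 100 × 60 × 15 mm — of a
soft matrix with up to eight non-overlapping spherical inclusions, two each
of diameters 3, 6, 9 and 12 mm. Materials carry four properties:

| property | healthy matrix (2 g agar / 100 mL) | tumor inclusion (8 g / 100 mL) |
|---|---|---|
| acoustic impedance | 1.59 MRayl | 1.92 MRayl |
| speed of sound | 1457 m/s | 1534 m/s |
| stiffness | 0.33 N/mm | 4.6 N/mm |
| attenuation | 1.25 dB/cm @ 16 MHz | 1.25 dB/cm @ 16 MHz |

The attenuation of the tumor agar is not separately characterised; both
materials use the same moderate 1.25 dB/cm, which only affects the common
path-loss factor and none of the detection contrasts.

The builder `make_reference_phantom()` places inclusions either on a fixed
canonical layout or by seeded rejection sampling, enforcing at least 10 mm
of planar clearance between sphere surfaces and 5 mm from the lateral
faces. Inclusion centres default to mid-thickness (z = 7.5 mm);
`bury_small = TRUE` sinks the 3 mm and 6 mm inclusions to z = 10 mm, the
configuration the full pipeline uses by default because small nodules in
real samples tend to sit deep. Exact inclusion coordinates are an open
degree of freedom — only their diameters and separation rules are fixed —
so positions are generated per seed rather than copied from any drawing.

### Homogenised stiffness

No closed-form contact model exists for a rigid flat probe over a sphere in
a soft slab, so the local reading is modelled as **two springs in series**
along the indentation axis. With block thickness $T$, inclusion chord $t$
under the probe, and pure-material stiffnesses $k_m$ (matrix) and $k_i$
(inclusion):

$$k_\mathrm{eff}(t) \;=\; \left(\frac{T-t}{T\,k_m} + \frac{t}{T\,k_i}\right)^{-1}.$$

This recovers both homogeneous limits exactly ($t=0 \Rightarrow k_m$,
$t=T \Rightarrow k_i$), increases strictly with the chord, and — because a
3 mm chord moves the reading only from 0.33 to about 0.41 N/mm while a
12 mm chord reaches about 1.28 N/mm — reproduces the masking of small
inclusions that limits palpation-only detection. Note that in this model
depth enters only through the chord: a deeply buried sphere is recorded as
deep, but its masking comes from its small chord, not its depth.

The chord is taken as the **maximum over the 3 mm probe face** (sampled on
a 0.5 mm sub-grid): a rigid face feels the stiffest column underneath. The
same footprint chord drives the acoustic model below, since the 3 mm
transducer face insonifies the same column; this also guarantees that a
2 mm grid cannot straddle a 3 mm inclusion without any point seeing it.

## The scan simulator

The simulator replaces the physical platform (motorised stages, load cell,
needle transducer, camera) while keeping its acquisition geometry and
parameters; `acquisition_config()` holds them all:

- indentation speed 0.5 mm/s; force trigger 0.2 N (low, to avoid damaging
  the sample); load-cell sampling 500 Hz, i.e. one sample per micrometre of
  travel; force noise SD 0.004 N (the load-cell resolution);
- transducer centre frequency 16 MHz, fractional bandwidth 0.25 at −6 dB,
  digitiser rate 1.6 GHz, recorded window 30 µs (the two-way path through a
  15 mm block is ≈ 20.6 µs, so the echo sits inside the window with
  margin); relative waveform noise SD 0.01;
- grid step 2 mm, probe diameter 3 mm.

**Indentation traces** are linear-elastic with a sharp contact point:
force is zero until a per-point contact offset (0.5–1.5 mm of approach
travel), then $F_z = k_\mathrm{true}(Z - Z_c)$ plus noise, ending at the
first sample at or above the trigger. Linearity is a deliberate
simplification: the stiffness estimator is a secant slope, so any monotone
force law would be recovered as some average slope; the linear law makes
recovery exact and therefore testable to machine precision.

**A-scans** contain a single Gaussian-envelope tone burst at the carrier
frequency. The envelope width follows from the −6 dB fractional bandwidth
($\sigma_t = \sqrt{2\ln 2}/(\pi\,\Delta f)\approx 94$ ns). The burst is
centred at the two-way time of flight through the layered column (matrix
and inclusion chord at their own speeds of sound) and scaled by the two-way
attenuation $10^{-2\alpha T/20}$ (in dB, path lengths in cm). When the
column crosses an inclusion the peak is reduced by the factor

$$1 - \delta \cdot t/D,$$

with $t$ the chord, $D$ that inclusion's diameter and $\delta$
(`inclusion_echo_drop`, default 0.5) the drop for a beam through the full
sphere. Normalising by the inclusion's own diameter (rather than the block
thickness) makes the *centre* of every inclusion — 3 mm or 12 mm — produce
the same strong echo drop, while rim points are graded by partial chords;
this is what makes the ultrasound channel sensitive to all inclusion sizes,
with its errors concentrated at inclusion rims. The measured amplitude
contrast between on- and off-inclusion echoes in physical phantoms is
reported only ambiguously (10% vs 60%), so the drop is a single
configurable parameter rather than a hard-coded constant. Air bubbles
trapped in an inclusion push the amplitude back toward the inclusion-free
value in proportion to `bubble_fraction` — the known ultrasound failure
mode — without modelling bubble acoustics.

With the echo drop set to zero and no noise, on- and off-inclusion A-scans
differ only in arrival time; since CIA compares window energies, which are
shift-invariant, CIA would then be blind. Detection by CIA in this
simulator is therefore driven by the amplitude contrast, by design.

**Randomness.** One master seed; every record draws from a substream
derived by stable integer hashing of (seed, point index, channel), so
re-ordering the grid never changes a point's noise, and all derived seeds
stay below $2^{31}$.

### What the simulator does *not* emulate

No beam diffraction, speckle, reverberation or B-mode imaging; no
viscoelasticity, Hertzian contact curvature or temperature dependence; no
backscatter from the inclusion itself (justified because the healthy/tumor
impedance step reflects $((1.92-1.59)/(1.92+1.59))^2 \approx 0.9\% < 1\%$
of intensity). Consequently, passing tests show that the *analysis chain*
is correct under its stated physics; they cannot certify performance on
real tissue, where rim diffraction, inhomogeneity and contact nonlinearity
will move the error rates.

## Vision stage

The camera sees the block as a bright rectangle on a textured stage
background. `subtract_background()` thresholds |sample − background| at a
fraction (default 0.1) of the difference's dynamic range — scale-free on
synthetic images — then applies morphological opening, keeps the largest
connected component and fills holes (EBImage). Orientation comes from the
second-order mask moments (angle of the dominant eigenvector, range
(−90°, 90°], near-isotropic masks defaulting to 0°);
`normalize_orientation()` rotates the mask upright about its centroid
(nearest-neighbour, then closing to smooth rasterisation staircases).

`build_indentation_grid()` anchors the lattice at the *moment-based*
bounding box — centroid minus half the moment extents
($W = \sqrt{12\,\mathrm{var}}$ for a rectangle) — which is sub-pixel
stable under re-rendering and rotation, unlike the raster bounding box,
whose ±1 px jitter would shift every grid point by half a millimetre. A
point is kept when its distance to the nearest background pixel is at
least `margin` (default 1.5 mm, the probe radius, so the probe face never
overhangs the edge; computed via a distance transform). Pixel convention:
pixel centres at half-integer mm, membership by centre inclusion, intervals
closed — a 10 × 10 mm square at 2 mm step and zero margin carries the full
6 × 6 = 36 lattice.

## Features, clustering, fusion, scoring

**Stiffness estimate.** $F_{z0}$ is the first sample at or above
`max(0.02 N, 5 × force_noise_sd)` scanning back from the trigger — on
clean traces identical to a forward scan, but immune to the rare
pre-contact noise excursion among the ~10⁷ pre-contact samples of a
seven-phantom experiment. The threshold sits well below the 0.2 N trigger
and above 5σ of load-cell noise. $F_{z\max}$ is the force at the trigger
sample.

**CIA.** Energies are summed over the full recorded window, ungated, as
the index is defined. The reference A-scan is the maximum-energy one:
without ground truth, the strongest plate echo is the best inclusion-free
proxy under the reflectometric model (an explicit reference index can be
forced). The reference's own CIA is exactly 0.

**Fuzzy c-means** (two clusters, fuzzifier $m = 2$, tolerance $10^{-5}$ on
the maximum membership change, ≤ 300 iterations) runs per phantom per
feature map — phantom replicas are scanned independently, so maps are not
pooled across phantoms before clustering. Centroids are initialised at the
25% and 75% feature quantiles (falling back to min/max when they
coincide): deterministic and permutation-invariant, so permuting the input
permutes the memberships and leaves the centroids untouched; a seeded
random initialisation remains available (`init = "random"`). Points
coinciding with a centroid take full membership there. The cluster with
the larger centroid is tumor — both features are constructed to increase
over inclusions — and exact 0.5 membership ties resolve to healthy. A map
whose values are all equal (up to float dust, threshold
$10^{-10}(1+|\bar x|)$) is degenerate; the pipeline surfaces this as an
all-healthy map with a warning rather than a failure.

**Fusion and scoring.** AND intersects, OR unites the tumor calls; by
construction FN(OR) ⊆ FN(stiffness) ∩ FN(ultrasound) and FP(AND) ⊆
FP(stiffness) ∩ FP(ultrasound). Ground truth labels a grid point tumor iff
it lies in the planar projected circle of any inclusion (boundary
inclusive, depth ignored — which is exactly what makes stiffness false
negatives over deep small inclusions possible). Confusion rates are
class-conditional: TP% and FN% are fractions of true-tumor points, TN% and
FP% of true-healthy points, each pair summing to 100. Replicated runs are
reported per phantom and pooled by summing counts; pooling counts and then
computing rates equals computing rates over the concatenated points.

## Problem sizes and runtime choices

The default end-to-end run uses the full reference geometry: a 320 × 320 px
scene at 0.5 mm/px, a ~1400-point grid, full-rate (1.6 GHz, 30 µs) A-scans.
One pipeline run takes on the order of ten seconds; the seven-replica
experiment about a minute. Unit tests that only exercise plumbing use a
40 × 30 mm single- or two-inclusion phantom and small grids; tests of the
physics keep the reference configuration. A-scan synthesis restricts the
burst to ±6σ of its envelope (the rest of the window is noise only), which
is exact to below 10⁻⁷ of the peak.

## Known limitations

- The series-spring stiffness model ignores lateral load spreading; depth
  of burial does not change the reading, only the chord does.
- The echo-drop parameter is phenomenological; its default (0.5 for a full
  diameter) spans the ambiguous measured contrast range rather than fitting
  either end.
- CIA here responds to amplitude only; any physical effect that preserves
  echo energy (pure delay, phase distortion) is invisible.
- The vision stage assumes a single convex sample well separated from the
  background; no learned segmentation.
- Confusion percentages obtained on simulated scans characterise the
  simulator's conditions, not physical phantoms; only the qualitative
  hierarchy (stiffness misses small inclusions; ultrasound finds all of
  them with rim errors; OR fusion detects every inclusion; AND minimises
  false positives) is expected to transfer.
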