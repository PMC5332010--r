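---
title: "Methods: the morphoscreen quantification stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the morphoscreen quantification stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`morphoscreen` reimplements the quantification stack of an image-based RNAi
screen for cell shape and YAP/TAZ nuclear translocation: segmentation,
sub-cellular region geometry, a fixed 126-feature single-cell profile,
five-way linear shape classification, plate normalisation with
control-referenced Z-score hit calling, and screen quality control. This
vignette is the package's account of the underlying models, the tunable
parameters, and the design decisions taken where the original pipeline
(built on proprietary screening software) leaves the algorithmic details
open.

## The synthetic data generator

Every downstream stage is validated against synthetic fields with complete
ground truth, so the generator's design determines what the tests can and
cannot show.

**Cell geometry.** Cells are smoothed star polygons: the boundary radius is
`r(θ) = R0 (1 + a·cos kθ + s·cos θ)`, where `k` is the protrusion count,
`a` the lobe amplitude and `s` a one-sided asymmetry, followed by an
area-preserving anisotropic stretch (elongation `e`). The five reference
morphologies are parameterised to be visually distinctive and linearly
separable in the extracted feature space (verified by test):

| class        | area (px²) | protrusions | amplitude | elongation | nucleus frac. | other |
|--------------|-----------|-------------|-----------|------------|---------------|-------|
| spindly      | 800–1000  | 2           | 0.30      | 4          | 0.20          |       |
| large spread | 2300–2900 | 6           | 0.06      | 1.1        | 0.12          |       |
| triangular   | 1000–1300 | 3           | 0.45      | 1.15       | 0.18          |       |
| fan          | 1000–1300 | 0           | 0.04      | 1.25       | 0.18          | asymmetry 0.4, nucleus offset 0.3 |
| small round  | 320–440   | 0           | 0.03      | 1          | 0.32          |       |

Areas are in pixels at the working magnification of the generator (a
20x-air-lens field is emulated at 1 pixel ≈ 0.65 µm, making a typical
spread cell a few thousand px²); they were chosen once, before any test was
run, to give the classes distinct area/roundness/axis-ratio signatures.

**Channels.** Hoechst marks the nucleus, α-tubulin and F-actin fill the
cell (with multiplicative smooth texture of amplitude 0.12–0.22), and the
YAP/TAZ channel is rendered flat and two-level — cytoplasm level `I`,
nucleus `ρ*·I` — so that the nuclear:ring mean-intensity ratio equals the
requested `ρ*` exactly before noise. This makes the generator its own
oracle for translocation recovery: any deviation measured downstream is
attributable to segmentation or region geometry, not to the render.

**Noise.** Poisson shot noise (photon gain 2 intensity units/count) plus
additive Gaussian read noise (σ = 2), the standard two-component
fluorescence camera model. Foreground levels of 100–160 units give an SNR
high enough that Otsu thresholding is unambiguous; noise robustness at low
SNR is *not* a claim the test suite supports.

**Fields and plates.** Cells are placed sequentially; non-contact
placements keep ≥ 1 px of background between cells, while designed contacts
(probability per placement) shift a new cell against an existing one and
clip the overlap, producing the zero-width shared boundary a
watershed-style space-filling labelling would give. Plates follow the
documented 384-well layout: positive controls on columns 23–24 (≥ 4 wells
per control), a density-dilution series on columns 1, 2, 23, 24 (cells
plated 250–2000, rendered at 12 cells per 1000 plated), mocks within
columns 3–22 / rows C–N. Control phenotypes: LATS1-like wells shift the
log10 nuclear:ring ratio by +0.3; YAP-like wells halve the YAP/TAZ channel
level; ECT2-like wells set the binucleation rate to 0.5 and shift the
mixture toward large-spread. One field per well by default (configurable).

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: point-spread-function optics, illumination
gradients, staining variability between plates, debris and segmentation
clutter, confluent monolayers, apoptotic morphology, and any true coupling
between cell density and YAP/TAZ localisation (the dilution series tests
the regression machinery, not the biology).

## Segmentation

The original screen's segmentation ran in proprietary software that names
only its inputs (nuclei from Hoechst, cytoplasm from α-tubulin seeded by
nuclei, border filtering). The package substitutes community-standard
equivalents with the same contract:

- **Nuclei**: Gaussian pre-smooth (σ = 2 px) → global Otsu threshold
  (overridable) → watershed on the distance transform (tolerance 1) to
  split touching nuclei → minimum-area filter (50 px²).
- **Cells**: the tubulin channel is smoothed and thresholded into a
  foreground mask (nuclei are always foreground); one cell label is grown
  per nucleus seed by intensity-guided propagation. A nucleus stranded
  outside the foreground keeps a 1-px-dilated copy of itself as its cell,
  with a warning. Equivalence with the original segmentation is not
  claimed — only contract-level equivalence, verified by IoU ≥ 0.8 against
  ground truth on synthetic fields.
- **Multinucleation** cannot be observed on nucleus-seeded cells (they are
  mononucleate by construction), so a cytoplasm-first pass labels connected
  components of the tubulin foreground and counts nucleus centroids per
  component; the multinucleate percentage is taken over nucleus-bearing
  components.

## Region geometry

Fractional borders are realised through a per-pixel normalised radial
coordinate: ρ(p) = |p − c| / |b(p) − c|, with c the mask centroid (pole of
inaccessibility if the centroid falls outside) and b(p) the boundary
intersection of the ray through p, sampled in 360 angular bins with
circular interpolation. Rays with several boundary crossings use the
outermost crossing, keeping ρ ≤ 1 inside any mask. This reproduces the
anchor cases exactly: an inner border at 100 % returns the whole cell, 0 %
is the edge, negative borders extend outside.

**The ring ambiguity.** The ring's outer border is specified as "20 % of
the distance from the cytoplasm edge to the inner border". Two readings are
defensible: (a) the outer border sits at depth 0.20 × 40 % = 8 % from the
edge, giving a ring spanning ρ ∈ [0.60, 0.92]; (b) it sits 20 % of the way
from the inner border back toward the edge, at depth 32 %, giving the much
thinner ρ ∈ [0.60, 0.68]. The package defaults to (a): it yields a
perinuclear annulus of thickness comparable to the nucleus — the stated
motivation for using a ring as the cytoplasmic reference — whereas (b)
gives a sliver of ~8 % of the radius. Reading (b) remains available via
`regions$ring_outer_from_inner` in the configuration; the default is never
switched silently. The ring always excludes the (uneroded) nucleus mask, so
nuclear and ring signal never share pixels.

**Nuclear erosion.** "Erode by 2 %" is read as a radius convention:
morphological erosion by `max(1, round(0.02 × equivalent radius))` px, with
fallbacks (1-px erosion, then the original mask with a warning) so the
region is never empty. Area and pixel conventions would give 1-px erosion
for all realistic nuclei as well; the choice is recorded here for users
comparing against the deposited tables.

**Membrane bands.** The 1-px inside and outside bands use 4-connectivity
(diamond structuring element), which keeps a digital disc's band area close
to its true perimeter 2πR. Only the *outside* band is clipped by
neighbouring labels; the inside band is purely geometric. This makes the
neighbour-fraction formula `NF = 1 − A1/(2·A2)` behave as intended: a fully
enclosed cell (A2 = 0) scores 1 by contract, and an isolated cell — whose
bands are nearly equal — sits near 0.5. Because that 0.5 floor is a
property of the formula, the package also reports a calibrated companion,
`1 − A2/A2geom` (the fraction of the geometric outside band occupied by
neighbours), which is 0 for isolated and 1 for enclosed cells and is
cross-checked in tests against a direct shared-boundary count.

## The feature registry

The screen's feature list totals "126 per cell, plus the neighbour
fraction", but the enumerated feature types over-count that total under any
literal reading. The registry therefore fixes the accounting as follows,
asserted by unit test:

| block | count | content |
|-------|------:|---------|
| morphology | 16 | area, roundness 4πA/P², moment-ellipse width/length, width:length for nucleus/cell/cytoplasm; protrusion-band area |
| intensity | 8 | YAP/TAZ mean over nucleus, eroded nucleus, ring, cytoplasm, cell; Hoechst (nucleus); tubulin (cytoplasm, cell) |
| ratios | 7 | nuc:ring and eroded-nuc:ring ratios with log10; nuclear YAP/TAZ per nuclear area; cell and nuclear area per whole-cell YAP/TAZ |
| SER | 80 | 8 responses × {tubulin, actin}×cytoplasm + {Hoechst, tubulin, actin}×nucleus × scales {0, 1} px |
| Haralick | 12 | correlation, contrast, variance, homogeneity × tubulin-cytoplasm, tubulin-nucleus, actin-nucleus |
| Gabor | 3 | mean / min / max over 8 orientations, actin cytoplasm |

Decisions embedded in this table: the listed "nuclear-intensity per nuclear
area" and "nuclear YAP/TAZ per nuclear area" ratios are read as the same
quantity (the former names no stain); the "nucleus region" YAP/TAZ
intensity is read as the eroded nucleus; the membrane band 1/2 areas and
the total-YAP/TAZ hit statistic `(nuclear + ring mean)/nuclear area` are
computed and carried as auxiliary per-cell columns outside the 126; and the
Gabor block is closed at three features (mean, minimum, maximum over
orientations). Well profiles are per-feature means over cells (missing
values ignored, with a per-feature missingness fraction attached), plus the
well-mean neighbour fraction as the 127th feature, cell counts and
shape-class counts.

Conventions worth naming because the original formulas are unpublished:
roundness is 4πA/P² with the perimeter estimated from exposed pixel edges
times π/4 (exact for digitised discs); width/length are the full axes
(4·√eigenvalue) of the mask's second-moment ellipse, which over-reads a
rectangle's side by ~15 % (documented, tested against the analytic moment
value); intensity "per area" ratios divide the region *mean* by the area.

## Texture features: numerical choices

**SER.** The image is convolved with a Gaussian and its derivatives at
σ = σ0 + s, σ0 = 0.5 px, scales s ∈ {0, 1}. All kernels are DC-free
(derivatives) and normalised to unit L2 energy — "normalised to within the
kernel" — so responses measure local structure irrespective of intensity
offset. With Hessian eigenvalues λ1 ≥ λ2: spot = ⌈−(λ1+λ2)⌉₊ where λ1 < 0,
hole its sign mirror, edge = |∇L|, ridge = ⌈−λ2 − |λ1|⌉₊,
valley = ⌈λ1 − |λ2|⌉₊, saddle = √(−λ1λ2) on sign-opposed pixels, and
bright/dark the rectified residuals ±(I − L). Because the original
constants are proprietary, correctness is defined by property tests —
pattern-response orderings (a blob at the matched scale maximises spot; a
line maximises ridge over spot and over the interior edge response; the
dark duals behave symmetrically) and translation invariance — not by
numeric equality to the deposited tables.

**Haralick.** Grey levels are quantised to 64 bins over the region's own
intensity range; the co-occurrence matrix at distance 1 px is symmetrised
and accumulated over the four directions, counting only pairs with both
pixels inside the region. Correlation of a constant region is undefined and
returned missing (contrast 0, homogeneity 1). The implementation is
required by test to agree *exactly* with an independent brute-force GLCM
enumeration on a suite of random 8×8 patches and masked regions.

**Gabor.** Eight orientations over [0, π), one wavelength (4 px, σ = 2 px,
isotropic envelope), quadrature pairs, DC-free and energy-normalised.
Per-pixel response magnitudes are reduced across orientations by mean, min
and max, then averaged over the cytoplasm. Oriented stripes drive max/min
anisotropy far above isotropic noise (tested as a paired comparison).

## Shape classification

A regularised one-vs-rest linear discriminant: features are z-scored with
the training statistics, constant features dropped (with a warning), class
indicator targets regressed with a ridge penalty (λ = 10⁻³ on the
standardised scale, closed form, deterministic), and cells take the argmax
score, ties broken by the fixed class order. There is no reject option —
every cell is classified exactly once, matching the screen's convention.
Missing features are imputed with training means and the cell flagged. The
training fixture mirrors the original's scale (~1,500 manually curated
cells → 300 synthetic cells per class), and an independent linear
discriminant (`MASS::lda`) serves as a cross-check in the test suite, never
as the implementation. Models serialise to a plain-text key-value file at
full double precision and round-trip bit-exactly.

## Screen statistics

"Normalised to each plate" is read as plate-wise centring and scaling,
using the population standard deviation (a three-well plate {1, 2, 3} maps
to {−1.225, 0, 1.225}); a robust median/MAD variant is available in the
configuration. Z-scores then use the mean and standard deviation of the
pooled mock-control wells of the screen, following the stated order
(normalise per plate, then score per screen); both the normalised and raw
columns are kept so users can score raw values instead. A well is a hit
when |Z| ≥ 1.5 — a sharp threshold, monotone in |Z|, with no
multiple-testing correction, deliberately: the screen's selection rule is a
plain threshold, and adding FDR machinery would change which wells are
called. Fold changes are computed on the raw scale against the control
mean. The dilution wells' plated densities travel in the gene-name column
(the deposited convention), are parsed back to numbers by the reader, and
feed an ordinary least-squares regression of the YAP/TAZ ratio on density.

## Quality control

Replicate-plate reproducibility: well-averaged feature vectors are z-scored
per plate, and the Pearson correlation between every well of plate A and
every well of plate B forms a matrix whose diagonal holds replicate
correlations and whose off-diagonal is the null; all off-diagonal pairs are
used. The "pairwise t-test" between the two sets is implemented as Welch's
two-sample t-test, since a pairing is undefined for unequal-size sets.
siRNA reproducibility compares replicate-well correlations against a null
obtained by permuting whole feature vectors across wells (preserving
within-vector covariance), with the median and the adjusted Fisher–Pearson
skewness reported for both. The Z′ factor is the standard
`1 − 3(σ₊+σ₋)/|μ₊−μ₋|`, annotated against the usual bands (> 0.3
acceptable, 0.5–1.0 desirable), undefined (missing, with a diagnostic) when
the control means coincide.

## Problem sizes and determinism

The validation suite runs at desk scale, chosen as the package's own
trade-off between statistical resolution and turnaround: synthetic fields
of 200–500 px with 1–30 cells; classifier validation with a 1,500-cell
training bank and 2,000-cell mixtures resampled from a 2,000-cell held-out
bank (resampling cells rather than re-rendering each mixture keeps the
check at the stated n while rendering each cell once); null hit rates over
twenty 2,400-well screens (the control mean/σ estimate is shared by every
well of a screen, so the Monte-Carlo standard error is taken across
independent screens, not across wells); and a 34-well demo plate in
duplicate for the end-to-end run. Every stochastic step is seeded — plate
wells derive independent substreams from the master seed, so simulating a
subset of wells reproduces the full-plate values — and identical seeds give
bit-identical images, tables and reports.

## Known limitations

- The pipeline is validated against its own generator; agreement with the
  original proprietary feature values is neither claimed nor checkable
  without the deposited images.
- Star-polygon geometry cannot represent concave or branched cells beyond
  its lobe parameterisation; the radial-coordinate bands assume
  star-shaped masks (outermost-crossing fallback otherwise).
- No illumination correction, PSF modelling or 3-D support.
- The neighbour fraction's raw form saturates at 0.5 for isolated cells by
  construction; use the calibrated variant for interpretable contact
  fractions.
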