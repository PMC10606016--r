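---
title: "Methods: energy reconstruction, death-zone metrology, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy reconstruction, death-zone metrology, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(applebruise)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, what the synthetic-data
generators emulate (and deliberately do not), and the numerical and design
choices made where the problem left them open.

## 1. Impact-energy reconstruction

A flat hammer of mass $m$ (default 0.5 kg) falls from height $h$ onto the
fruit with an array pressure sensor on its face (default 40 × 40 sensing
points at 1.9 mm pitch, 60 fps). Writing $F(i,j,f)$ for the calibrated
force at grid point $(i,j)$ in frame $f$ and $Z$ for the frame rate, the
package computes

$$V_1 = \sqrt{2 g h}, \qquad
V_f = V_1 - \frac{1}{mZ}\sum_{x=1}^{f-1}\sum_{i,j} F(i,j,x), \qquad
S_f = V_f / Z,$$

$$E(i,j) = \sum_{f} F(i,j,f)\, S_f .$$

Assumptions, stated explicitly:

* **Free fall to first contact.** $V_1$ is the ideal free-fall speed;
  guide-rod friction and air drag are ignored.
* **Gravity neglected during contact.** The impulse balance uses the
  measured contact forces only, exactly as the formulas are written.
* **Frame-start velocity.** $S_f$ uses the velocity at the start of frame
  $f$, not a midpoint value. This overestimates the work integral for a
  decelerating hammer; the package quantifies the bias (below) rather than
  silently "improving" the printed formula.
* **No restitution.** The velocity series is truncated at the first
  non-positive $V_f$ (with a warning). Continuing would make $S_f$
  negative and subtract energy, which contradicts the non-negative energy
  maps the method is meant to produce; rebound simply is not modelled.

**Effective frames.** The contact window is assumed contiguous. Leading and
trailing frames whose *total* force is at or below a floor (default 0.1 N —
small against the forces of interest, robust to sensor noise) are trimmed;
frames inside the window that dip below the floor are kept as contact
chatter. An all-quiet recording raises a "no contact" error rather than
returning an empty stack.

**Calibration.** The sensor vendor's calibration procedure is not public,
so the package uses a per-point affine model $F = g_{ij} \cdot \mathrm{raw}
+ b_{ij}$, floored at zero, fit from a uniform-load calibration block. A
global calibration is the special case of constant $g, b$.

**Discretization error, bounded not guessed.** Because the synthetic
sensor integrates within each frame (frame force = mean of fine-step
forces), the frame-boundary velocities of the reconstruction are exact, and
the energy error obeys the provable bound

$$|E_\mathrm{recon} - E_\mathrm{true}| \;\le\; \frac{1}{m Z^2}\sum_f
\bar F_f^2,$$

which the test suite checks against an independent trapezoidal work
oracle on randomized simulations. At 60 fps and the default soft-contact
world this is a relative error of roughly 8–10 %, falling as $1/Z$.

**Impact centre.** The centre is the grid argmax of $E$, ties broken
toward the grid centroid (the maps of interest are single-peaked). The
slice orientation (row vs. column) is a parameter, since either may be
aligned with the fruit's axis in practice.

## 2. Death-zone segmentation and metrology

Stained sections show dead cells in blue against pale pulp; section
preparation itself kills scattered cells everywhere, so colour *saturation*
— not blueness — is the discriminant for the concentrated death zone. The
pipeline is: HSV conversion → S channel → threshold → opening → closing →
largest 8-connected component → hole filling.

Choices the problem left open, and how they were fixed:

* **Threshold:** Otsu's method on the S channel by default (reproducible,
  parameter-free), with a manual override. The threshold actually used is
  recorded in the mask's provenance.
* **Structuring elements:** disks, radii 3 px (open) and 5 px (close) by
  default — small relative to a ≥ 0.3 mm band at typical micrograph scales
  (≈ 0.02 mm/px), large enough to erase the 1–2 px stain speckle.
* **Connectivity:** 8-connected for foreground labeling; hole filling
  fills background regions (4-connected) not reaching the image border.
* **Peel tracing** is not standardised anywhere, so the package uses a
  per-column first-crossing of a tissue score (saturation × value, computed
  after a 3 × 3 channel blur — on a gray slide background, unblurred pixel
  noise reads as spurious saturation), smoothed by an 11-column running
  median whose shrinking end windows are replaced by a local linear fit.
  This is documented as an extension point, not a claim about the original
  workflow.

**Depth and width.** Per image column, foreground runs along the depth
axis are encoded half-open — a run occupying pixel rows $a..b$ contributes
boundaries $(a, b{+}1)$ — so that summed widths match the boundary
differences exactly and no ±1 px ambiguity survives. With boundaries
$Y_1 < \dots < Y_{2k}$: centre $= (Y_1 + Y_{2k})/2$, depth $=$ (centre −
peel) × scale, width $= \sum (Y_{2r} - Y_{2r-1}) \times$ scale. For $k=2$
this is exactly the centre $(Y_1+Y_4)/2$ and width $(Y_2-Y_1)+(Y_4-Y_3)$
convention; for more runs it generalises as "midpoint of the outermost
boundaries, sum of all run widths". Depth is measured along the image
column (the literal reading of the measurement figure), not along the local
surface normal; a normal-distance mode is explicitly out of scope. Columns
with no detected zone can be treated either as missing or as depth-zero
sites (`undefined_as_zero`), the latter mirroring how sensing points below
the yield force are treated.

## 3. Registration and correlation

The damage profile (mm, image frame) is resampled by linear interpolation
onto the 1.9 mm sensor pitch and aligned with the energy profile either
from metadata offsets (default; the generator records the true offset) or
by aligning the depth peak with the energy peak. Pearson's $r$ is the
default correlation (the plain reading of "correlation coefficient"), with
Spearman as an option; a zero-variance series yields a flagged undefined
$r$, never a silent `NaN`. Sub-yield masking removes points whose *peak
frame force* (the chosen temporal statistic) stayed below the yield force —
8.75 N by default for real fruit, or the generator's scaled
yield-equivalent in synthetic studies (see §5).

## 4. The synthetic world

### Drop-impact simulator

The hammer dynamics are $m\ddot\delta = -F_c$, with a Hertzian spring plus
optional linear damping, $F_c = \max(0, k\delta^{3/2} + c\dot\delta)$,
integrated by RK4 at a fine step (default ≈ 10 µs) from $\dot\delta(0) =
\sqrt{2gh}$ and stopped at the hammer's rest point. The total force is
spread over the grid with the Hertz pressure profile $p(r) \propto
\sqrt{1 - r^2/a^2}$, contact radius $a = \sqrt{R_\mathrm{eff}\,\delta}$,
and downsampled to frames by within-frame averaging. Ground-truth
per-point energy is the fine-step work accumulation.

**The defaults are a numerical stand-in, not apple physics.** A genuinely
fruit-like stiffness makes a 0.5 kg free hammer stop in a few
milliseconds — under one 60 fps frame — in which case no frame-wise
reconstruction is meaningful; conversely, per-point forces near the 8.75 N
yield value would require contact pressures far beyond fruit strength.
These constraints cannot all hold at once for any stiffness. The package
resolves the tension in favour of the *method*: defaults
($k = 50$ N m$^{-3/2}$, $c = 2$ N s m$^{-1}$, $R_\mathrm{eff} = 3$ mm)
give a contact lasting ~13 frames at 60 fps and a patch spanning ~20
sensing points, the regime in which the reconstruction formulas are
informative, at the price of non-physical penetration depths. Calibrated
apple material properties are a non-goal; every test that depends on scale
uses the generator's own recorded truth.

### Section renderer

Renders, with exact ground truth: a gray glass background; a pale
low-saturation tissue mosaic whose cell size switches from fine (< 1.2 mm
below the peel — the epidermis/sclerenchyma zone) to coarse parenchyma
beyond, implemented as a jittered block tessellation (a cheap stand-in for
a Voronoi mosaic; only its S-channel statistics matter downstream); a
circular-arc peel; sparse 2 px blue speckle (section-prep cell death); and
a saturated blue band centred $d(x)$ below the peel with thickness $w(x)$,
absent over configurable gap intervals. Depth profiles must stay ≥ 1.2 mm
where the band exists — the zone forms in the pulp, never the peel. Noise
is i.i.d. Gaussian per channel plus speckle density, both scaled by one
`stain_noise` level (package sweep: 0.02 / 0.05 / 0.08).

What the renderer does **not** emulate: stitching artefacts, stain
gradients and wash unevenness, out-of-focus blur, cut-induced tears, or
cell-level instance structure. A green segmentation test therefore
establishes correctness of the algorithmic chain on images with the right
colour statistics and geometry — not robustness to real histology.

### Coupled samples

A coupled sample ties the two observables together with known truth:

$$d(x) = d_0 + \alpha\,E(x) + \varepsilon, \qquad
\varepsilon \sim N(0, \sigma(h)^2), \qquad
\sigma(h) = \sigma_0\, h_\mathrm{ref} / h,$$

on the sensing points whose peak force reaches the yield-equivalent
threshold; the band is absent elsewhere. Width is drawn log-normally,
independent of energy — the null relation the analysis should (and does)
report as $|r| \approx 0$.

Two deliberate choices:

* **$E(x)$ is the *reconstructed* (frame-rate) energy profile**, not the
  fine-step truth: the claimed relation in the field is between the
  *measured* energy distribution and depth, and this makes the noise-free
  sample an exact linear relation end to end ($r = 1$ to machine
  precision), which the acceptance suite asserts at $10^{-6}$. Through the
  rendered-image route the same sample recovers $r$ only up to pixel
  quantisation (~0.5 px), which is why the exact-coupling check runs on
  the analytic profile and the image route is held to Jaccard/RMSE
  criteria instead.
* **Stated constants, chosen once** from the simulator's measured scales
  (per-point peak energies of ~7–15 mJ and peak forces of ~0.25–0.3 N
  across the 50–200 mm height range): $\alpha = 250$ mm/J and $d_0 =
  1.2$ mm put depths in the observed 1.2–5 mm range;
  yield-equivalent $= 0.02$ N sits where low drops leave an appreciable
  sub-yield fringe; $\sigma_0 = 0.2$ mm at $h_\mathrm{ref} = 0.2$ m
  encodes the larger apple-to-apple scatter at low heights. These are the
  package's stated world; they are not adjusted per test.

One empirical subtlety, found and kept: with the heavy low-height noise,
*including* the zero-depth sub-yield sites can raise the pooled $r$ (two
well-separated clusters correlate strongly) even though those sites break
the exact within-support relation. The masking test therefore asserts the
mechanism deterministically — on a noise-free low-height sample, masking
restores $r = 1$ exactly while the unmasked pairing falls short — rather
than a Monte-Carlo sign that depends on the noise level.

## 5. Numerical and interface conventions

* Indices $i, j$ and frame numbers are 1-based; sensing point $n$ sits at
  $(n-1) \times 1.9$ mm along its axis; image column $x$ is centred at
  $(x-\tfrac12) \times$ scale.
* Long-format frame CSVs (`frame,i,j,force_raw`) are the canonical
  interchange; per-frame grid CSVs are also read. Forces are written with
  `%.17g` so a write–read round trip is bit-exact. Sparse zeros are
  omitted; the first and last frame are always anchored so the frame count
  survives.
* Images are PNG with a JSON sidecar (`scale_mm_per_px`, `peel_side`); no
  TIFF reader exists in the supported R stack, so TIFF support is out of
  scope.
* Resampling guards support-edge membership with a $10^{-6}$-pitch
  tolerance (grid positions accumulate floating-point drift), and grid
  points interpolated across an internal gap of the measured profile stay
  undefined.
* All generators restore the caller's RNG state; a sample is fully
  determined by its parameters and seed, and a study run writes
  timestamp-free outputs so identical configurations are byte-identical.

## 6. Known limitations

* The simulator's parameter regime is numerically convenient, not
  biophysically calibrated (see §4); absolute correlation values from the
  synthetic study are not comparable to values measured on real fruit.
* Depth is a per-column distance, which overestimates the normal distance
  under strong peel curvature.
* The segmentation invariant of exactly one connected component means a
  bruise that is truly split laterally will be reported only by its
  largest piece; lateral gaps *within* the retained component are handled.
* Pearson's $r$ is reported without significance testing, matching the
  scope of the analysis it implements; regression modelling of depth on
  energy is out of scope.
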