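---
title: "A 4-D digital MRI phantom for liver motion: model and methods"
author: "phantom4D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 4-D digital MRI phantom for liver motion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phantom4D synthesizes time-resolved (4-D) abdominal MR image series with a
known, controllable respiratory motion ground truth. Its intended users are
developers of 4-D MRI reconstruction, deformable registration and tumor
tracking methods, who need image series where the true deformation of every
voxel is available for validation. This vignette explains the model, the
parameters that matter, the numerical choices, and what the phantom does and
does not emulate.

## The simulator in one paragraph

A parametric anatomy builder rasterizes a labelled chest–abdomen volume at
end of exhalation (EOE) on a 256 × 256 × 150 grid of isotropic 1.6719 mm
voxels (axes: +x left, +y anterior, +z superior). Each structure belongs to
one of four categories that determine how its T1-like appearance is
synthesized. A hypointense spherical tumor (radius 1.5 cm) is embedded in
the upper liver. A respiratory motion model assigns each structure a
fraction of the preset diaphragm (SI) and chest (AP) amplitudes, modulated
in time by a periodic amplitude curve; the resulting forward deformation
vector fields (DVFs) are repaired, inverted, and used to pull the reference
volume to each of 10 phases of the 5 s cycle, for three breathing presets
(large 3.0/2.0 cm, normal 2.0/1.2 cm, limited 2.0/0.5 cm diaphragm/chest
amplitude).

## Structure categories and texture synthesis

The structure table assigns each structure a category, intensity constants
A and B (arbitrary units), and motion fractions. The shipped defaults are
in `inst/extdata/structures.yaml` and `defaultStructureTable()`.

* **Category I — key textured organs** (liver, gallbladder, pancreas,
  spleen, stomach, kidneys, and the three-part heart). Each organ gets a
  uniform base intensity A plus a *detail* volume: a donor organ texture is
  deformably registered onto the phantom organ mask (mask-driven Demons,
  below), resampled, and linearly rescaled so the detail mean equals B.
  The organ mean is therefore exactly A + B (liver: 95 + 160 = 255). The
  rescaling is purely multiplicative, preserving zero and relative
  contrast.
* **Category II — large soft-tissue volumes** (muscle, body, static marrow,
  intestine wall). Textured by iterative patch transplantation: 5³-voxel
  patches are drawn at random from a donor muscle region of interest and
  copied into randomly chosen fully-unassigned 5³ sites of the structure
  until no site fits, then 3³ patches, then single voxels, so every voxel
  is assigned exactly once; a 5³ moving average restricted to the structure
  then smooths patch seams. Compositing again uses A + detail(B).
* **Category III — air-associated structures** (lungs, airway tree,
  intestinal air, esophagus wall, background air). Uniform intensity A;
  the lungs and intestinal air additionally receive i.i.d. Rayleigh noise
  with mean 5 (scale σ = 5·√(2/π)), emulating background magnitude noise.
* **Category IV — bone** (ribs, spine, cord, cortical bone, cartilage,
  mobile marrow). In the reference volume these voxels are first textured
  as part of the adjacent muscle or body region (majority label in a
  2-voxel dilation shell decides which). At *every* phase — including the
  reference — they are overwritten with their uniform intensities using the
  phase's own warped label masks. This sidesteps the DVF discontinuities
  that inevitably appear at bone/soft-tissue interfaces.

The tumor is inserted last: inside radius r the texture is blended toward
the local liver mean (taken over a 3 cm ball) with the quartic radial
profile Δ(ρ) = Δ₀(1 − (ρ/r)²)², Δ₀ = 100, so the centre intensity is
exactly the local mean minus 100 and the rim transition has zero slope.
The profile is a fourth-order polynomial chosen to satisfy the
smooth-transition constraint; the half-depth iso-surface sits at
ρ = r·√(1 − 2^(−1/2)) ≈ 8.11 mm.

## The donor texture

Real patient scans are not shipped; the donor is procedural: a Gaussian
random field with 4 mm correlation length, mean 100 and SD 15 (clipped at
0), with darkened quasi-tubular vessel tracks inside the donor liver, and a
48 mm cubic muscle ROI for pattern generation. Donor organ masks are the
phantom organ shapes perturbed by per-axis scalings in [0.94, 1.06] and
±4 mm translations, painted with the same precedence carving as the
phantom anatomy (so the donor liver has the same renal impression and
gallbladder fossa as the phantom liver — without this the registration's
volume error is dominated by the un-carved concavities). Everything is
deterministic given the seed. A user can substitute a real labelled scan
through the NIfTI/MetaImage ingest path.

## Respiratory motion model

The amplitude fraction is an asymmetric squared sinusoid, m(t) = sin²(πt/4)
for 0 ≤ t < 2 s (inhale) and cos²(π(t−2)/6) for 2 ≤ t < 5 s (exhale):
continuous, periodic, 0 at EOE, 1 at end of inhalation (EOI, t = 2 s).

Each structure moves rigidly with velocity
v_s = (0, +κ_ap·A_ap·m(t), −κ_si·A_d·m(t)) (inhalation: inferior liver
motion, anterior chest motion). The liver fractions are calibrated to the
reference tumor excursion of the normal series: κ_si = 1.92/2.0 = 0.96 and
κ_ap = 1.10/1.2 = 11/12. Other organs carry plausible, config-overridable
defaults (stomach 0.80, spleen 0.85, pancreas 0.70, kidneys 0.60, lungs
0.50, intestine 0.55, heart 0.55 SI / 0.10 AP, muscle/body 0.10, bones,
cord and static marrow 0). The anterior body wall moves at the full AP
amplitude, as a weight field that fades in over 40 mm from the mid-coronal
plane and tapers over 25 mm into the surrounding air (air carries no
signal, so this costs nothing visually and keeps the skin/air interface
smooth).

The piecewise-rigid field is blended by Gaussian smoothing (σ = 5 mm per
component); then the exact rigid velocity is re-imposed inside each
category I organ eroded by 6 mm (linear ramp across the annulus), and the
spine complex and cortical bone are ramped back to exactly zero over the
same depth. Because the tumor is placed at least 27 mm inside the liver,
it always lies in the rigid core: its ground-truth motion is an exact
rigid translation, which is what makes the kinematic end points well
posed.

Three construction details keep the forward map invertible (diffeomorphic)
for the normal and limited presets, and they were the decisive design
problems of this phantom:

1. **Cushioning.** A fast organ directly touching near-static tissue
   compresses the σ = 5 mm transition into a slope > 1 (folding). The
   anatomy therefore wraps every fast abdominal organ in ≥ 16 mm of
   intestine (an adaptive dilation of the organ union), the spine complex
   in a slow body sleeve, and keeps the rib cage 10+ mm away from the
   compartment; organ velocities are painted on 6 mm-dilated masks so the
   transition lives in the cushion, not in the rigid annulus.
2. **Contact relaxation.** Where two category I organs with different
   fractions genuinely touch (kidney against the liver's renal impression,
   heart on the dome), the rigid pinning is relaxed over 12 mm and the
   Gaussian blend carries the transition.
3. **Thin bones.** Ribs, cartilage and mobile marrow are too thin to carry
   a ramp to exact zero without a cliff; they retain the small bled motion
   of their surroundings. Their appearance is re-rendered per phase from
   the warped labels anyway, so no visual artifact results — this mirrors
   the known behaviour of NURBS-derived reference DVFs, which are
   discontinuous at bone surfaces.

The **large** preset (3.0 cm diaphragm motion) locally exceeds the
invertibility limit of the 5 mm blend near the liver–lung and chest-wall
interfaces around peak inhalation: the forward map truly folds in thin
zones there. The pipeline still renders the series (the inverter returns
its best-effort field with a classed warning); the residual bound below is
guaranteed only for the normal and limited presets.

## DVF repair, inversion, warping

Synthetic fields are passed through the same morphological repair the
reference DVFs of the original workflow required: a voxel whose component
deviates from its 3³-neighbourhood median by > 2 mm, while ≥ 20 of the 26
neighbours agree with that median within 0.5 mm, is an isolated hole/spur
and is replaced by the median (at most two sweeps; idempotent).

Backward fields are obtained by the fixed-point iteration
u_b(x) ← −u_f(x + u_b(x)), run under-relaxed (ω = 0.6) from a
half-resolution initial guess, at most 50 fine-level iterations, stopping
when the largest update falls below 0.01 voxel. The under-relaxation is
essential: the plain iteration oscillates wherever the coupled y/z
displacement Jacobian has spectral radius ≥ 1 (liver dome and posterior
corners), which happens well before the map itself loses invertibility.
The composition residual ‖u_f(x + u_b(x)) + u_b(x)‖∞, over voxels whose
pullback stays in-grid, is required to stay below 0.05 voxel; normal-preset
phase fields converge to < 0.01 voxel.

Phase volumes are rendered by tricubic (Catmull–Rom) backward warping —
exact at grid nodes, reproduces linear ramps — with out-of-grid pullbacks
filled with the air intensity 40; labels use nearest-neighbour pullback.
Per phase, category IV voxels are overwritten with their uniform
intensities from the warped labels, the reference static-marrow texture is
re-inserted unchanged, a 3³ moving average fuses the one-voxel dilated
spine/marrow interface shell, and a weighted 5³ kernel (truncated Gaussian,
σ = 1.25 voxels, normalized) smooths everything outside that shell.

## Mask-driven Demons registration

Category I texture mapping and the organ-geometry-variation workflow use a
multiresolution Demons registration between *masks*. The masks are
represented as clamped signed-distance images (cap 12 mm, negative
inside): unlike smoothed indicator images, these have a nonzero gradient
over a wide band and graded interior values, so the force vanishes exactly
at alignment instead of leaving the interior free to drift (with
indicators the overlap stalls around Dice 0.96 regardless of iterations).
The update is the classic normalized Demons force with, by default, the
symmetric (two-sided) gradient; each update is fluid-smoothed (σ = 2
voxels) and the accumulated field diffusion-smoothed (σ = 1 voxel),
coarse-to-fine over 4×/2×/1× levels with 100/50/25 iterations. Pyramid
levels at which the structure would shrink below ~6 voxels are skipped
(their iterations move to the finest level) so small organs do not vanish
from the coarse images. Support volumes and Dice are evaluated on the
warped *binary* moving mask (partial-volume threshold 0.5); the 0.5 level
set of a smoothed indicator shrinks badly for small structures. On the
native grid the seven organ mappings reach Dice 0.97–0.995 and a mean
|volume difference| of ≈ 0.5%.

## Tumor measurement

The segmentation surrogate for manual contouring thresholds the depression
below the local liver background at half the tumor depth (50), inside a
search ball centred on the nominal rigid tumor trajectory. The candidate
region (0.55 × the 30 mm ball) and the background shell (0.55–0.85 × ball)
are kept inside the liver by the placement clearance, so lung or bowel
voxels can never contaminate the background median or the connected
component. The neighbourhood is evaluated 2× supersampled, which makes
volume and centre-of-mass estimates sub-voxel accurate instead of
lattice-quantization limited. By construction this surrogate tracks the
half-depth iso-surface (~2.2 cm³), not the full 1.5 cm sphere
(14.1 cm³ analytic), so its *absolute* volume is smaller than a manual
contour of the full sphere would give; its phase-to-phase stability and
centre-of-mass excursion are the meaningful quantities. On the native grid
the normal-preset series yields an EOE→EOI excursion of 1.92 cm SI /
1.10 cm AP and a segmented volume stable to a few hundredths of a cm³.

## Problem sizes and reproducibility

All randomness (donor field, vessels, patch placement, Rayleigh noise)
derives from the run seed through R's RNG, and a fixed seed reproduces the
reference volume bit-for-bit. The test-suite builds use the coarse
64 × 64 × 48 demonstration grid and the 128 × 128 × 75 half-resolution
grid; the acceptance script measures the kinematic end points and the
category I mapping on the full native grid and the 10-phase volume
stability at half resolution. Coarser grids keep all physical lengths in
mm (only the sampling gets coarser); at the demonstration scale the 5³
smoothing kernel spans 33 mm, which flattens the 15 mm tumor's depression
below the half-depth rule — demo-scale runs are pipeline exercises, not
measurement runs.

## What the synthetic data do and do not show

The generator emulates: organ-scale T1 contrast (Table-style A/B means),
spatially correlated soft-tissue texture, patient-like organ topology with
carved contacts, quasi-rigid liver motion with a realistic amplitude
hierarchy, magnitude-noise in air-filled structures, and bone handling
faithful to reference-DVF workflows. It does not emulate: k-space
acquisition or reconstruction effects (no coils, sequences or aliasing),
intra-organ deformation gradients (motion is piecewise rigid with blended
transitions), hysteresis (inhale and exhale retrace one spatial field),
cardiac motion, desynchronized or irregular tumor trajectories (the tumor
inherits the liver field; a per-tumor fraction override exists as a hook),
and sliding interfaces (the blend is volumetric). Passing tests therefore
demonstrate correctness of the geometry, texture statistics, field
synthesis/inversion and measurement chain — not realism of MR physics.

## Known limitations

* The large-amplitude preset folds locally (documented above).
* The anatomy is parametric-geometric, not anatomical; acceptance metrics
  (volumes, COM shifts) are anatomy-independent by construction, and real
  labelled anatomies can be ingested instead.
* The exact-zero bone invariant holds in deep bone cores only.
* The Fig-style animated previews are PNG mid-slices per phase; no GIF
  encoder is bundled.
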