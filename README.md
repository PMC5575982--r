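# phantom4D

A four-dimensional computerized MRI phantom for liver motion studies, as
an R package. It builds a labelled chest–abdomen anatomy at end of
exhalation (256 × 256 × 150 voxels, isotropic 1.6719 mm), synthesizes
T1-like MR texture per structure category, embeds a hypointense spherical
liver tumor (r = 1.5 cm), and warps the reference volume through a 5 s
respiratory cycle into 10-phase 4-D image series for three breathing
presets — with the underlying deformation vector fields available as
ground truth. It is aimed at developers of 4-D MRI reconstruction,
deformable registration and tumor-tracking methods who need image series
whose true motion is known exactly.

## The model in brief

Structures fall into four categories: (I) key organs textured by
deformably mapping a donor organ texture onto the phantom mask and
compositing a uniform base A with a detail volume rescaled to mean B
(organ mean A + B; liver 95 + 160 = 255); (II) large soft-tissue volumes
textured by iterative transplantation of 5³ → 3³ → 1³ donor patches, each
voxel assigned exactly once, then a 5³ moving average; (III) air-filled
structures with uniform intensity plus Rayleigh noise of mean 5 in lungs
and intestinal air; (IV) bone, re-rendered with uniform intensities at
every phase from warped label masks. The tumor's radial profile is the
quartic Δ(ρ) = Δ₀(1 − (ρ/r)²)², Δ₀ = 100.

Motion: every structure moves rigidly by a fraction (κ_si, κ_ap) of the
preset diaphragm/chest amplitudes, modulated by the periodic curve
m(t) = sin²(πt/4) (inhale) / cos²(π(t−2)/6) (exhale); the piecewise field
is Gaussian-blended (σ = 5 mm), re-imposed exactly inside eroded organ
cores, inverted by damped fixed-point iteration, and applied by tricubic
backward warping. The liver fractions (0.96 SI, 11/12 AP) are calibrated
so the normal-breath series reproduces a 1.92 cm SI / 1.10 cm AP tumor
excursion between end of exhalation and end of inhalation. Mask-driven
Demons registration (multiresolution, fluid + diffusion smoothing, on
clamped signed-distance images) performs the category I texture mapping
and the organ-geometry-variation workflow. See
`vignettes/phantom-methods.Rmd` for the full account.

## Worked example

Build the normal-breath series on the half-resolution grid (128 × 128 ×
75 @ 3.3438 mm; the full grid takes a few minutes) and measure the tumor:

```r
library(phantom4D)

series <- build4DSeries("normal", halfResGrid(), seed = 7)
kin <- measureTumorKinematics(series)
round(kin$per_phase[, c("time_s", "volume_cm3", "com_y", "com_z")], 3)
#>    time_s volume_cm3   com_y   com_z
#> 1     0.0      0.477 209.807 171.517
#> 2     0.5      0.449 211.304 168.740
#> 3     1.0      0.458 215.283 161.850
#> 4     1.5      0.458 219.121 155.060
#> 5     2.0      0.477 220.773 152.372
#> 6     2.5      0.486 220.048 153.718
#> 7     3.0      0.477 217.937 157.159
#> 8     3.5      0.458 215.283 161.850
#> 9     4.0      0.453 212.452 166.742
#> 10    4.5      0.486 210.450 170.309

c(SI = kin$si_shift_cm, AP = kin$ap_shift_cm, dV = kin$max_volume_dev_cm3)
#>      SI      AP      dV
#> 1.91450 1.09664 0.02804
```

Phase 1 is end of exhalation, phase 5 end of inhalation: the segmented
tumor's centre of mass travels 1.91 cm inferiorly (`com_z` falls from
171.5 to 152.4 mm) and 1.10 cm anteriorly, matching the calibrated
1.92/1.10 cm excursion to within half a millimetre, and its segmented
volume is stable to ±0.03 cm³ across the cycle. (The segmentation tracks
the half-depth iso-surface of the tumor profile — about 0.5 cm³ at this
resolution, 2.2 cm³ at full resolution — not the full 14.1 cm³ sphere;
see the vignette.)

On the native 256 × 256 × 150 grid the same measurement gives
SI = 1.9203 cm, AP = 1.1025 cm, with segmented volumes of 2.233 and
2.219 cm³ at the two extreme phases.

Other entry points:

```r
ref <- buildReference(defaultGrid(), seed = 7)   # labels + textured EOE volume
ref$mapping                                      # per-organ Dice / volume error
writeVolume(ref$volume, "reference.nii.gz")      # NIfTI-1 / .mha output
writePhaseSeries(series, "series4d.nii.gz")      # one 4-D file, or a directory
previewSlices(phaseVolume(series, 5), "p5")      # mid-slice PNGs
```

A command-line front end ships in `inst/scripts/phantom4d.R`:

```sh
Rscript inst/scripts/phantom4d.R build-4d --preset normal --seed 7 --out out/
Rscript inst/scripts/phantom4d.R make-demo --out demo/   # coarse CI-scale run
```

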