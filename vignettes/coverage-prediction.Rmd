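---
title: "Predicting MRgHIFU target volume coverage: models and methods"
author: "hifucover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MRgHIFU target volume coverage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifucover)
```

## The problem

Magnetic-resonance-guided high-intensity focused ultrasound (MRgHIFU) ablates
deep pelvic tumours noninvasively, but only where an unobstructed acoustic
path exists from the transducer to the focus. Bone and air block ultrasound;
organs at risk must not sit in the beam. Candidate patients are referred on
supine diagnostic imaging, yet the treatment happens in a very different,
oblique-supine-decubitus position on the HIFU couch, with the body pressed
into a coupling gel-pad. A large fraction of referred patients turn out to be
untreatable only after a dedicated screening scan in the treatment position.

`hifucover` implements a quantitative alternative: simulate the treatment
device over a labelled image volume and compute, voxel by voxel, which part
of the target the focus can reach — both on a dataset acquired in the
treatment position and, predictively, on a referral dataset reoriented into
that position. Comparing the two quantifies how well the referral scan
predicts treatability.

## Device model

The device model follows a Sonalleve-V2-class system:

* **Couch geometry.** The transducer's home position lies 140 mm below the
  magnetic isocentre; the undeformed oil-bath membrane lies 72.5 mm below
  the isocentre, so the calibrated membrane-to-home distance is
  140 − 72.5 = 67.5 mm (`couch_geometry()`).
* **Transducer.** A 256-element phased array, 130 mm aperture, 140 mm focal
  length, 1.22 MHz. Element centres are placed on the spherical cap whose
  curvature centre is the focus, so each element is exactly one focal length
  from the focus. The element arrangement on the cap is not part of the
  device specification that matters here (only ray directions do); we use a
  deterministic Fermat-spiral (sunflower) layout, which gives near-uniform
  area density, with a concentric-ring alternative behind a config option.
* **Pose space.** Translations up to ±72.5 mm left-right (LR) and
  inferior-superior (IS), +34/−33 mm anterior/posterior (AP), and tilt up to
  ±10° in 2.5° steps about the IS axis (left-right tilt only; IS tilt is
  excluded to avoid running the beam off incomplete registered slices, and
  is not modelled). The sweep translates in 4 mm steps for whole-pelvis
  targets and 2 mm for small tumour targets (`pose_limits()`).
* **Treatment cell.** An 8 mm × 21.84 mm ellipsoid centred at the focus,
  long axis along the beam (`treatment_cell()`), the idealized ablation
  volume of one sonication.

Two modelling decisions were genuinely open and are worth recording. The
tilt pivot is the transducer apex (a gimbal under the dish); with a 140 mm
arm, 10° of tilt displaces the focus 24.3 mm laterally and 2.1 mm
posteriorly. And AP translation is swept over its full mechanical range,
while LR/IS are restricted to the target extents (`target_search_bounds()`)
— restricting AP as well is possible through `pose_limits()` but is not the
default, since the AP axis is how the positioner reaches targets at
different depths.

## Coverage computation

For one dataset the computation (`compute_coverage()`) is:

1. Build a grid of one point per target voxel (voxel centres).
2. Enumerate the pose grid (LR × IS × AP × tilt, deterministic order).
3. For each pose, discretize the beam into 256 rays (element centre →
   focus), sample each ray every 0.2 mm from the element up to but
   excluding the focus, and map every sample to its nearest voxel. If any
   sample of any ray lands on bone, extracorporeal air or an organ at risk,
   the pose is discarded (*any-ray-blocked* rule; a tolerated blocked-ray
   fraction is available but defaults to 0). Samples outside the image are
   unobstructed — they lie in the oil bath or couch below the imaged
   volume.
4. For each clear pose, mark all target grid points inside the treatment
   cell as covered. The covered flags only ever accumulate, so the result
   is independent of pose order.
5. Report `CV` (covered voxels × voxel volume), `TV`, and
   `tvc_pat = 100 · CV / TV`.

For a referral/treatment pair, the treatment covered set becomes the
reference: `tvc_vol = 100 · |CV_regref ∩ CV_treat| / |CV_treat|`, computed
voxel-wise on the shared treatment grid.

One property of the model deserves emphasis: rays are tested only up to the
focus, but the cell extends 10.92 mm beyond it. A focus placed just outside
an obstruction can therefore legitimately ablate a short distance past it.
Consequently a target is only unreachable when its shielding is thicker
than the cell half-length — the package's tests construct their
zero-coverage scene accordingly.

The pose sweep is the hot loop and is implemented in compiled code
(`src/sweep.cpp`), with per-tilt beam clouds precomputed in fractional
voxel coordinates so each pose costs one translated pass with early exit on
the first obstructed sample. A plain-R re-implementation in the test suite
(`oracle_coverage()`) must agree with it voxel-for-voxel.

## Registration

Referral datasets are mapped into treatment orientation by a 12-parameter
affine fitted by least squares to ≥ 10 paired bony landmarks
(`fit_landmark_affine()`; a rigid Kabsch fit is available for sensitivity
checks). Full affine rather than rigid is deliberate: the clinical
registration tooling this emulates computes an affine. Quality is
quantified as the mean Euclidean distance between corresponding points
(`registration_error()`). Images are resampled trilinearly, masks by
nearest neighbour so labels stay binary (`apply_transform()`).

## Segmentation

The body outline (`segment_body_outline()`) is found by Otsu thresholding
on a 256-bin histogram: a first threshold separates air from tissue, and a
second threshold, restricted to the foreground histogram, separates the
gel-pad from the body. The second split is only applied when the foreground
histogram is genuinely bimodal, judged by Otsu's effectiveness ratio
(between-class variance over total variance ≥ 0.8) — a supine dataset has
no gel-pad and must not have its body histogram split in half. 3D
connected-components labelling (6-connectivity) keeps the largest
above-threshold component, then slice-wise morphological closing (2-voxel
disc) and hole filling in axial planes produce a single filled outline,
incorporating dark internal structures such as bone marrow cavities or
bowel gas.

Extracorporeal coupling air (`segment_extracorporeal_air()`) is a
deliberately simple interface rule: below-threshold voxels outside the
body, within a 10 mm band below the skin's under-surface, in columns whose
band actually contains gel-pad material — columns where the body overhangs
plain air beyond the pad's lateral edge are not part of the coupling
interface. `coupling_extent()` reduces this to the LR interval of coupled
skin used to clip the transducer search.

Quality metrics are the Dice similarity coefficient (`dice()`) and the
symmetric mean contour-to-contour distance (`mean_contour_distance()`),
computed slice-wise in axial planes by default (matching slice-based manual
validation) with a 3D mode available. Contours are boundary voxels with at
least one face-adjacent background neighbour.

## Transducer positioning from referral imaging

For a treatment dataset the isocentre — hence the home position — is known.
For a registered referral dataset the AP coordinate of the home position
must be estimated (`find_skin_point()`, `estimate_home_position()`): drop a
vertical line from the treatment isocentre to the skin, then walk the
deformation chain

```
home_AP = skin_AP − t + b − 67.5
```

down through the compressed gel-pad (thickness *t*), up by the membrane
bowing (*b*) to the undeformed membrane plane, and down the calibrated
membrane-to-home distance. The defaults *t* = 9.8 mm and *b* = 10.0 mm are
the volunteer-cohort averages of the bundled measurement tables
(`cohort_tables()`, `volunteer_deformation_averages()`). The chain is
linear, so assumed-versus-true errors propagate exactly as
Δhome = Δb − Δt; this is unit-tested and also exercised end-to-end. A
15 × 15 mm neighbourhood-sampling refinement of the skin point is
implemented (`neighborhood_mm`) but off by default, as it has not been
shown to help. Skin position is resolved to the nearest voxel centre, so
home estimates carry up to half a voxel of AP quantization.

Note that with the full ±33/34 mm AP translation range available, a
moderate home-position error is often *compensated* by the positioner —
the reachable envelope shifts but still covers the target. The error
becomes visible exactly when an envelope boundary or an obstruction
binds; the end-to-end test pins AP translation to expose the mechanism.

## The digital pelvis phantom

All test data are generated (`generate_phantom()`,
`make_referral_treatment_pair()`): an elliptic-cylinder body resting on a
compressed gel-pad over a bowed membrane, a pelvic-ring bone shell with one
angular gap emulating the acoustic window at the sciatic notch, a spherical
~17 mm tumour near the isocentre (≈ 20,600 mm³, the patient target scale),
optional organ-at-risk ellipsoids, optional lens-shaped air defects at the
skin/gel-pad interface, and a pelvic tilt about the IS axis in the 6–33°
range observed clinically. Class-mean intensities (air 50, bone 150, gel
700, body 1000) receive seeded Gaussian noise (SD 20). Everything is
deterministic given the spec and seed, and the generator emits exact
ground-truth masks, ≥ 10 bony landmarks on the ring, and a truth record.

Two profiles are used throughout: `desk` (192 × 160 × 96 voxels at 1.5 mm),
the working scale for the pipeline and the acceptance script, and `mini`
(48³ at 3 mm) for oracle-equivalence and property tests, where an
independent naive sweep must match the engine exactly.

What the phantom does *not* emulate matters for interpreting results: MR
contrast and bias fields, Rician noise, anatomical shape variation,
soft-tissue deformation between positions (the referral and treatment
phantoms are rigidly related apart from couch-side construction), and
partial-volume mixing at boundaries. Segmentation and registration metrics
on the phantom are therefore near-perfect (Dice ≈ 1.0, registration error
≈ 0 without injected noise) — passing them shows the algorithms are
implemented correctly, not that clinical images would score as well;
clinical body-outline segmentation of this kind has been reported around
Dice 0.99 and interface-air segmentation around 0.89.

## Numerical conventions

* World frame: right-handed, mm; LR = x (array axis 1), AP = y (axis 2,
  positive anterior/up on the couch), IS = z (axis 3, positive superior).
  Axis-aligned volumes only; NIfTI files are written with a diagonal sform.
* Voxel-centre convention with 1-based indices (R idiom): the world
  coordinate of voxel (1,1,1) is the origin.
* Nearest-voxel mapping uses `floor(x + 0.5)` — half-away-from-zero for the
  positive fractions that arise here — rather than banker's rounding, so
  the compiled engine, the R helpers and the test oracles share one
  deterministic tie rule.
* Ray sampling includes the element endpoint and excludes the focus
  (`floor(length / spacing)` points per ray); the focus lies inside the
  target, which must not block itself.
* Pose grids are anchored at the home position (translation 0) and step by
  `translation_step`; a non-empty search interval that contains no step
  multiple falls back to its midpoint rather than returning no poses.
* Degenerate inputs fail loudly: empty targets, unimodal images offered for
  body segmentation, singular affines, < 4 or coplanar landmarks, empty
  treatment covered sets (reported as `NA` agreement in the pipeline).

## Limitations

The package predicts *geometric* reachability only. Acoustic propagation,
aberration, attenuation and thermal dose — which determine what can
actually be ablated safely — are out of scope, as are DICOM handling,
oblique acquisitions, deformable registration, and bone/OAR/tumour
segmentation (consumed as masks, reflecting a manual-contouring workflow).
Cohort-level clinical agreement figures cannot be reproduced here because
the underlying imaging data are not publicly available; the package instead
validates every mechanism on synthetic data with exact ground truth.
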