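---
title: "Simulating and validating aOCT airway volumetry against CT"
author: "aoctair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and validating aOCT airway volumetry against CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoctair)
```

## Scope and model

`aoctair` implements the quantitative pipeline used to validate
endoscopic anatomical OCT (aOCT) as a volumetric modality for the nasal
airway: helical-scan simulation, lumen reconstruction, CT-side
processing, rigid registration, field-of-view matching, and overlap
metrics, together with the embedded 24-comparison cadaveric study table
and its summary statistics. Because the cadaveric scans themselves are
not public, the package's experimental substrate is a synthetic phantom
whose ground truth is known analytically; the study table is the only
real data shipped.

The acquisition model is purely geometric. An aOCT frame is a set of
first-surface radial detections: for rotation rate $f$ (Hz), pullback
speed $v$ (mm/s) and pullback length $L$ (mm), the helix pitch is
$p = v/f$ and the frame count is $\lfloor L/p \rfloor + 1$ (at the
defaults 20 Hz, 6 mm/s and 20 mm: $p = 0.3$ mm and 67 frames; the
physical A-line rate, 100 kHz, gives 5000 A-lines per revolution, which
the simulator downsamples to a configurable 360 working angles). No
interferometric physics is modelled — no speckle, axial point-spread
function, or sub-surface signal; the simulator produces exactly what the
downstream segmentation consumes, a radius and a validity flag per
(frame, angle).

## The phantom

The phantom lumen is a star-convex radial function around a straight
centerline aligned with the airflow/pullback axis,

$$ r(\theta, z) = R(z)\,\big(1 - s\,\cos^2_+(\theta - \pi)\big)
   - T(\theta, z) + \varepsilon(\theta, z), $$

where $R(z)$ is the nominal radius carrying a Gaussian valve
constriction (fractional depth `valve_depth` at `valve_z_mm`, axial FWHM
`valve_width_mm`), $s$ flattens the septal side, $T$ is a
turbinate-like medial protrusion, and $\varepsilon$ is a small seeded
harmonic roughness (default RMS 0.1 mm) that keeps segmentation and
registration from being trivially exact. A straight centerline is
appropriate because the probe path through the cartilaginous vault has
no tight curves, and it keeps ray casting and the ground truth analytic.

Defaults — length 30 mm, base radius 4 mm, valve at 10 mm with depth
0.3 and width 6 mm, septal flattening 0.25, turbinate amplitude 0.8 mm —
were chosen once so the lumen volume lands in the 800–2500 mm³ range of
adult nasal airways reported in the study table; they are a plausible
stand-in, not measurements. Voxelization is isotropic at 0.33 mm (the
CT voxel size), with air = 1 and tissue = 0; a scalar export maps air to
−1000 and tissue to 40 so thresholding is exercised on CT-like values.
Voxelization uses slab-centered axial sampling and 3×3 in-plane
supersampling with majority vote, which makes the voxelized volume
converge to the analytic volume as the voxel shrinks (asserted at 0.66
vs 0.33 mm in the tests).

The probe trajectory runs along the centerline (optionally offset
in-plane) and is rejected with an informative error if any sample comes
closer to the wall than the probe radius (0.43 mm, half the 0.86 mm
catheter outer diameter). `apply_graft_widening` emulates the
cross-sectional effect of spreader/butterfly grafts as an exact in-plane
morphological dilation restricted to an axial interval; dilation is
monotone, so treated-slice CSA can only grow.

What the phantom deliberately does not emulate: curved probe
trajectories, bilateral (two-cavity) anatomy, soft-tissue-envelope
deformation between scans, and anatomically realistic turbinate/septum
shapes. Passing the end-to-end tests therefore demonstrates the
pipeline's internal consistency under the acquisition's geometric
artifacts, not clinical accuracy on real heads.

## Scan artifacts

Three artifact mechanisms are modelled, each named after its clinical
counterpart:

* **Range fold-over.** Walls beyond the maximum imaging radius
  $r_{\max}$ (12 mm) appear mirrored: a true distance $d$ with
  $r_{\max} < d \le 2 r_{\max}$ is detected at $2 r_{\max} - d$ and
  flagged aliased; beyond $2 r_{\max}$ the sample is invalid. The mirror
  form is the standard conjugate-ambiguity behaviour; the reconstruction
  attempts no de-aliasing, so folded walls shrink the reconstructed
  volume — exactly the effect the comparison metrics must quantify.
* **Sensitivity roll-off.** Signal is modelled as a linear dB decay,
  $-\alpha d$ with slope `rolloff_db_per_mm` (default 1.5 dB/mm) against
  a detection floor (default −30 dB); distant walls drop out. A small
  uniform dropout probability (default 0.02) stands in for everything
  else that makes walls locally undetectable. The real system's roll-off
  curve is not published, so both knobs are configuration, and the tests
  assert only the monotone property (dropout fraction non-decreasing in
  the slope).
* **NURD.** Nonuniform rotation is applied as an angular resampling
  $\theta' = \theta + a\,\phi(\theta)$ per frame, with $\phi$ a seeded
  sum of harmonics 1–3, zero-mean over a revolution and normalized to
  unit maximum; radii values are untouched, only their angular
  assignment distorts. No NURD correction is applied anywhere, matching
  the processing chain being emulated.

Shadowing needs no separate model: rays return the *first*
air-to-tissue crossing, so proximal structures inherently occlude distal
ones. Ray marching steps at half a voxel with 8 bisection refinements at
the crossing, localizing the voxelized wall to well under a tenth of a
voxel; the dominant residual error is the voxelization itself (up to
about half a voxel plus a sub-voxel sampling offset, which is why scan
tests use a 0.25 mm bound rather than exactly half a voxel).

## Reconstruction

Frame segmentation is radius-based: valid samples are median-filtered
over a 5-sample circular window; angular gaps up to `max_gap_deg`
(default 45°, a package decision — the original processing was manual
and unspecified) are bridged by linear interpolation of radius versus
angle; larger gaps are closed by a straight chord and recorded, so
downstream code can see how much of a contour was guessed. A frame with
fewer than three valid samples is unsegmentable and raises an error.

Contours are rasterized in their frame-transverse plane at 3×3
subsamples per 0.33 mm voxel (an effective 0.11 mm in-plane resolution
before the common grid), assigned to output slices by nearest frame
along the pullback axis, and stacked into an isotropic binary volume;
the surface is the boundary-voxel-face mesh. Reconstruction is
translation-equivariant by construction (the output grid is anchored to
the contour bounding box), which the tests assert bit-for-bit.

## CT-side processing

The airflow axis is defined by two landmarks (naris/choana analogs),
with a PCA-of-air-voxels fallback; resampling onto an isotropic grid
perpendicular to that axis uses nearest-neighbour lookup for masks and
trilinear interpolation for scalar volumes. Segmentation is
threshold-plus-connectivity: voxels below the threshold, restricted to
the 26-connected component of a seed point, so detached air pockets are
discarded. The CSA profile is a per-slice air-voxel count times the
in-plane voxel area, which conserves volume exactly
($\sum_k A_k \,\Delta z = V$, asserted in the tests).

The INV estimate is the argmin of the CSA profile after a 3-slice moving
average — a guard against single-voxel noise minima; the window is a
package decision and configurable. Ties break to the most anterior
slice, the search range defaults to the anterior third of the profile
(the cartilaginous-vault analog), and the reported area is the raw value
of the selected slice. On a monotone profile the argmin sits at the
range boundary; that is documented edge behaviour, not an error.

## Registration, clipping, metrics

Registration is rigid ICP on surfaces: point-to-point iterations with
the closed-form Kabsch update, multi-started from the identity, centroid
alignment, and the best proper principal-axes matching (the start with
the lowest final RMS wins — with partial overlap a single PCA
initialization is unreliable), followed by a point-to-plane refinement
against the fixed mesh's vertex normals. The refinement matters on
voxel-face meshes: their stair-step lattice creates shallow local minima
under point-to-point correspondences that the normal-projected update
escapes. Convergence is declared when the RMS improves by less than
$10^{-4}$ mm, with a 100-iteration cap and a warning (never an error) on
non-convergence. Registering surfaces and then resampling the moving
binary volume by nearest-neighbour inverse mapping is the package's
reading of "least-squares distance minimization" between volumes;
Taubin mesh smoothing is available (`smooth_mesh`) but deliberately not
used before registration, where it was found to blur the minimum.

Field-of-view clipping zeroes the CT mask beyond the registered aOCT
mask's posterior, cranial and caudal extents and touches nothing in the
anterior, medial or lateral directions. All comparison metrics are
computed *after* clipping: the volume difference is CT − aOCT (also as
percent of CT), DSC is $2|A\cap B|/(|A|+|B|)$ (defined as 1 when both
masks are empty), and HD is the full symmetric maximum — not a
percentile — over boundary-voxel centers of masks or vertices of
meshes, with per-point distances returned for colormap rendering.

## Study table and summary conventions

The embedded table carries the 24 donor/side/condition comparisons with
their CT and aOCT volumes, DSC and HD; its md5 checksum is asserted on
load. Summaries report the mean and *sample* standard deviation (n−1) of
per-record differences; the percent summary is the mean of per-record
percentages, not the ratio of mean volumes. Both conventions were
verified to reproduce the published values at display precision before
being frozen (population SD does not). Display rounding follows the
published precision: one decimal for mm³, percent and HD, two for DSC.
Excluding the one NURD-degraded comparison (donor 4, left, post
butterfly graft) is exposed through the `exclude` argument keyed by
record id.

## Problem sizes and runtime choices

The test suite and acceptance script run the full pipeline on the
default phantom (about 45×45×91 voxels at 0.33 mm, 67-frame scans at
360 angles), with Monte-Carlo properties (NURD degradation, metric
oracles) at 5–100 replicates; these sizes were chosen so a complete run
finishes in a couple of minutes on one CPU while leaving every claim
property-tested rather than spot-checked. Nearest-neighbour queries and
the 26-connected flood fill are the only compiled components (Rcpp);
everything else is vectorized R.

## Known limitations

* The phantom's realism is geometric, not anatomical; results on it
  bound the pipeline's algorithmic error, not clinical error sources
  such as soft-tissue displacement between CT and aOCT sessions.
* The radius-based frame segmentation is a reimplementation choice; the
  original study segmented frames in interactive software by an
  unspecified procedure.
* HD is surface-based and uses the full maximum; volume-based or
  percentile variants would give systematically different values.
* The simulator's roll-off and NURD parameters are not calibrated to a
  physical system; only their qualitative, monotone effects are
  asserted.
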