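---
title: "Quantifying ulnar-sided wrist kinematics from dynamic CT bone surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ulnar-sided wrist kinematics from dynamic CT bone surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulnakin)
```

## The measurement problem

Two dynamic disorders dominate ulnar-sided wrist pain: ulnocarpal impaction,
where the ulnar head abuts the lunate or triquetrum during motion, and distal
radioulnar joint (DRUJ) instability, where the radius subluxates palmarly or
dorsally around the ulnar head. Both are positional: a static scan in neutral
can look normal while the abnormality appears only at the extremes of motion.
Four-dimensional (dynamic) CT captures the moving bones — typically ten
reconstructed volumes per second — and, once each bone is segmented and
tracked, the joint relationships can be measured in every frame.

`ulnakin` implements the measurement half of that workflow. Its inputs are
per-bone triangle surface meshes (radius, ulna, lunate, triquetrum, capitate)
in millimetre coordinates — from STL/PLY files or isosurfaced from an integer
label volume — together with either per-frame rigid poses or per-frame point
clouds to register against. Its outputs are four parameters per frame, each
plotted against a movement-specific wrist angle:

* **3-D ulnar variance (uv3d, mm)** — proximodistal height difference between
  the most distal point of the ulnar head articular surface (styloid removed)
  and the most distal point of the radial sigmoid notch, measured along the
  longitudinal axis of the radius frame. Positive = ulna longer ("ulna-plus").
* **Ulnocarpal proximity (ucp_l, ucp_t, mm)** — the shortest 3-D
  surface-to-surface distance from the ulna to the lunate and to the
  triquetrum. The realizing site pair is reported because the location of the
  closest approach migrates with wrist position.
* **3-D modified radioulnar line (mru3d, %)** — the perpendicular distance
  from the most palmar point of the ulnar head to the palmar-radial line
  (palmar-radial corner to palmar notch margin), as a percentage of sigmoid
  notch width. Dorsal dislocation of the radius relative to the ulnar head is
  positive.
* **3-D epicentre (epi3d, %)** — the offset of the ulnar epicentre (the
  intersection of the ulna's longitudinal axis with its distal cortex),
  projected onto the palmar–dorsal notch chord, from the chord midpoint, as a
  percentage of notch width. Same sign convention.

Delta values (`d_*` columns) express each parameter relative to the neutral
frame, chosen as the frame with minimum absolute wrist angle (ties go to the
earliest frame); deltas at the neutral frame are exactly zero.

## Coordinate conventions

All measurements are expressed in the anatomical frame of the radius:
`e_ru` radial→ulnar, `e_pd` palmar→dorsal, `e_lon` proximal→distal, a
right-handed orthonormal triple. The sagittal plane is spanned by
(`e_pd`, `e_lon`), the coronal plane by (`e_ru`, `e_lon`) and the axial plane
by (`e_ru`, `e_pd`). Left wrists are mirrored across the sagittal plane into
the right-hand convention (`frame_normalize_side()`) before anything is
measured, so dorsal-positive and ulnar-positive signs mean the same thing for
both sides.

Wrist angles are signed: extension, radial deviation and supination are
positive; flexion, ulnar deviation and pronation negative. During
flexion–extension (FE) the angle is the sagittal capitoradial angle (capitate
long axis versus radius long axis, both projected into the sagittal plane);
during radioulnar deviation (RUD) the coronal capitoradial angle; during
pronation–supination (PS) the axial-plane angle between the radius'
mediolateral axis and the ulnar axis through the styloid tip and the
epicentre. The ulnar axis is taken in the epicentre→styloid sense so that its
axial projection points ulnarly and the neutral ulnoradial angle is near
zero; the connecting line is the same either way, this only fixes the zero of
the angle scale.

## Landmark detection

Automatic landmarking drives all four parameters:

* **Styloid removal.** The ulnar styloid is the most distal part of the ulna;
  its tip is the vertex maximizing the `e_lon` projection. Vertices within a
  cylinder of radius 4 mm (a typical styloid base width; configurable) around
  the axis through the tip parallel to `e_lon` are excluded, and the most
  distal remaining vertex is the distal ulnar articular point.
* **Sigmoid notch by curvature classification.** Surface curvature is
  computed per vertex and thresholded at 0.1 / mm — concave positive — inside
  a search window (distal 25% of the radius' longitudinal extent, ulnar half
  of its radioulnar extent; both configurable). The window suppresses other
  concave regions of the radius such as the fossae of the distal articular
  surface. The largest face-connected component above threshold is the notch;
  its most distal vertex is the radial point of the ulnar variance
  measurement.
* **Margins and corner.** The palmar and dorsal notch margins are the extreme
  notch-region vertices along `e_pd` (ties resolved to the deepest vertex of
  that rim column); the notch midpoint is exactly their mean. The
  palmar-radial corner is the most palmar vertex of the distal radius rim
  radial to the notch (ties resolved to the most distal vertex). These are a
  geometric surrogate for landmarks that production pipelines obtain from a
  statistical shape model of the radius; a file-based override
  (`landmarks_read()`, `detect_landmarks(provided = ...)`) accepts externally
  computed landmarks for fidelity studies.
* **Epicentre.** The dominant principal axis of the ulna's vertex cloud,
  oriented distally, is cast through the mesh; the farthest intersection
  along `e_lon` is the ulnar epicentre.

### Which curvature?

The package implements two per-vertex curvature estimators behind one switch
(`curvature_mode`): the cotangent-Laplacian **mean** curvature with one-ring
barycentric areas, and a **longitudinal** normal-section curvature. The
latter treats every one-ring edge as a chord estimate of the normal
curvature along that edge's tangential direction, fits the second
fundamental form per vertex by least squares (Euler's theorem; weighted by
squared edge length, which damps the noise amplification of very short
edges), and evaluates it along `e_lon`. A consistency gate flags vertices
whose axis-aligned chord estimates disagree strongly — the signature of a
crease or mesh edge, where a normal-section curvature is undefined — as
`NA`, exactly like boundary vertices. The classified notch region is
additionally cleaned by a one-ring morphological opening, which removes
single-vertex spurs of the jagged discrete classification boundary without
moving the boundary itself.

The default for notch classification is the longitudinal mode. The sigmoid
notch is a shallow trough: strongly curved along the proximodistal direction,
only gently curved palmar–dorsally. Its longitudinal normal-section curvature
is therefore close to the reciprocal of the trough's arc radius
(about 0.15–0.25 / mm), comfortably above the 0.1 / mm threshold, whereas the
*mean* curvature — the average of both principal directions — is roughly half
that and straddles the threshold for anatomically plausible notch depths. A
cylindrical concavity of radius 5 mm, the canonical test case, has
longitudinal curvature 0.2 / mm under this reading. Both estimators remain
available and tested (`mean_curvature()`), and the classification itself is a
strict threshold either way.

Sign convention, fixed throughout: curvature is measured with outward
normals and concave (hollow) regions are positive, so a convex sphere of
radius r has mean curvature −1/r and the notch is positive. This makes the
0.1 threshold reproducible: the notch is the only strongly concave region in
the search window.

## Registration and tracking

Static high-resolution segmentations are registered to each dynamic frame
with point-to-plane iterative closest point (`rigid_register()`):
correspondences by nearest neighbour, rejection of residuals above three
times the median (robustness to partial overlap), linearized point-to-plane
solve per iteration, rotation re-projected onto SO(3), at most 100
iterations, convergence when the RMS residual changes by less than
10⁻⁴ mm. Each frame is initialized from the previous frame's pose, matching
the smoothness of a 10 Hz acquisition; frames whose residual exceeds twice
the dynamic-voxel diagonal (2·|(0.59, 0.59, 0.50)| mm) are flagged. This is a
mesh-level surrogate for the image-intensity registration used in production
imaging pipelines; on the synthetic data it recovers poses to well under
0.1 mm and 0.5° at realistic noise (about half a voxel of vertex jitter).

Landmarks are detected **once**, on the static meshes, and transported by
each frame's rigid transform — never re-detected per frame. This matches the
static-segmentation-plus-registration design and removes per-frame detection
noise from the parameter trajectories.

## Cohort summaries

Per-wrist series are pooled by `bin_by_angle()`: samples are binned by wrist
angle (default 5°), each wrist contributes one value per bin (its mean within
the bin — the documented, switchable choice; pooling all frames would weight
wrists by how long they linger in a bin), and the cohort summary is the
median with interquartile range across wrists, using linearly interpolated
(type 7) quartiles. Bins visited by fewer than `min_count` wrists (default
22) are masked and report nothing, reproducing the convention of displaying
only the range of motion achieved by a minimum number of wrists.
`normality_gate()` applies a Shapiro–Wilk test at α = 0.05 per sample;
non-normal samples are reported as median/IQR (the default reporting path),
normal ones may use mean/SD. `write_summary_table()` assembles the
movement-by-position table (extreme positions from the nearest populated
bin, ranges as per-wrist max − min summarized across wrists) with cells
formatted to one decimal, `"median (q1 to q3)"`.

## The synthetic wrist

No public dynamic-CT wrist dataset exists, so validation runs on a
parametric phantom (`generate_wrist()`) whose every landmark and parameter
is known analytically from the construction:

* the **radius** is an extruded rounded-rectangular shaft; the sigmoid notch
  is a circular-arc trough carved into the flat ulnar face (longitudinal
  normal-section curvature exactly 1/R over the whole facet, R from the
  prescribed depth and extent). The trough's flat floor continues 0.4 mm
  beyond the margin columns before the end wall drops, so the margin
  vertices are smooth interior vertices while the wall crease sits on its
  own dedicated column (whose curvature is undefined and flagged by the
  estimator's consistency gate). Mesh columns are placed exactly at the
  margins and the midline, and refined rows sit just proximal to the distal
  rim, so the curvature classifier terminates exactly at the prescribed
  margins (the detected notch width equals the prescribed width to within
  hundredths of a millimetre) and the detected distal point sits within one
  refined row (0.08 mm) of the rim. The palmar face is oblique, making the
  palmar-radial corner a unique vertex;
* the **ulna** is a cylindrical shaft capped by a hemispherical head, with
  the styloid process as a smooth radial bump whose tip is an exact mesh
  vertex. The prescribed ulnar variance fixes the head apex height relative
  to the notch rim; the neutral pose puts the epicentre exactly over the
  notch midpoint, so the epicentre parameter is zero by construction;
* **lunate and triquetrum** are spheres whose centres lie along exact
  head-vertex directions with their pole vertices facing back along the gap
  line; because both meshes are inscribed in their spheres, the prescribed
  gaps are attained *exactly* by that vertex pair and bounded below
  everywhere else, so the ground-truth proximities are exact, not
  approximate;
* the **capitate** is an elongated ellipsoid whose long axis is the exact
  ground-truth capitate axis.

The phantom's notch is deeper relative to its width than a real sigmoid
notch, a deliberate exaggeration that keeps the facet's curvature comfortably
above the 0.1 / mm classification threshold at the default width of 18 mm.
Default prescriptions (neutral ulnar variance −0.4 mm, ulno-lunate gap
3.2 mm, ulno-triquetral gap 6.9 mm) and the cohort variability draws in
`generate_cohort()` are centred on values reported for healthy adult wrists.

`simulate_motion()` poses the phantom through FE (capitate rotation about
`e_ru`), RUD (about `e_pd`) and PS (radius and capitate rotation about the
ulna's long axis), with coupling functions for ulnar-variance drift,
dorso-palmar DRUJ translation and carpal approach. Default couplings are
calibrated to healthy-cohort magnitudes: the PS translation spans 15.2% of
notch width, FE and RUD 7.7% and 9.3%; ulnar variance varies by about 0.6 mm
over FE (quadratic, the observed non-linear trend), 0.4 mm over RUD, and
*decreases* about 1.1 mm toward both PS extremes (3-D measurements do not
show the pronation increase that projectional radiographs report).
Triquetral proximity swings several millimetres (largest in ulnar deviation
and pronation) while lunate proximity stays nearly constant — the
approach-function slopes interpolate the reported healthy extremes. One
deliberate simplification: a single dorso-palmar translation drives both DRUJ
parameters, so the phantom's mru3d and epi3d ranges coincide (calibrated to
the epicentre range), whereas in vivo the radioulnar-line range is larger;
the linear-response law (below) is what validates both measurements.
`degrade()` adds seeded vertex jitter and decimation to the per-frame
targets — emulating dynamic-scan quality at about half the 0.59 × 0.59 ×
0.50 mm voxel — without touching ground truth.

Because carpal motion is realized along the exact gap lines and the PS
rotation axis passes through the epicentre, the analytic ground-truth series
are exact, not discretized: any pipeline-versus-truth discrepancy beyond
mesh tolerance is a pipeline defect.

## What the tests show — and what they cannot

The test suite validates, among others:

* exactness of the distance kernel against an exhaustive triangle-pair
  brute force (50 random mesh pairs, 10⁻⁹ mm);
* closed-form curvature (sphere 1/r at two refinement levels, plane, saddle)
  and the 1/r scaling law;
* the linear-response law: an imposed dorsal ulnar translation t changes
  both DRUJ parameters by −100·t/W within 1 percentage point for t up to
  4 mm, and an imposed distal translation d changes ulnar variance by
  exactly d;
* rigid-motion invariance of all five parameters (< 10⁻⁶ under 100 random
  joint motions) and left–right mirror consistency;
* end-to-end recovery on 30 seeded wrists per movement (noiseless): RMSE
  below 0.1 mm for ulnar variance and proximities, 1.5 percentage points for
  the DRUJ parameters, 1° for wrist angles;
* ICP pose recovery within 0.5° / 0.1 mm in ≥95% of 100 trials at 0.25 mm
  vertex noise.

Passing these shows the *measurement chain* is correct and stable under the
geometry, noise and motion regimes the phantom emulates. It does not certify
performance on real anatomy: real bones have cortical texture,
segmentation artefacts, anatomical variants (notch obliquity, volar tilt,
styloid variants) and soft-tissue-constrained kinematics that the convex
phantom does not model. In particular the curvature-based notch detector and
the fixed search windows are the components most sensitive to anatomical
variation; the landmark-override path exists precisely so a
statistical-shape-model landmarker can replace them without touching the
parameter definitions.

## Numerical choices and degenerate inputs

* Quartiles: type 7 (linear interpolation), stated because reported IQRs
  depend on it at small n.
* `classify_uv()` calls |uv| < 1 mm neutral; the boundary value 1.0 mm is
  assigned outward (non-neutral).
* Landmark ties (e.g. a flat distal rim) break deterministically — lowest
  vertex index, after the documented secondary keys — so detection is
  bit-reproducible.
* Interpenetrating surfaces report zero proximity with a warning; an
  epicentre projecting beyond 150% of the notch width from the midpoint
  warns of gross dislocation; near-degenerate angle projections (axis within
  5° of the plane normal) warn.
* Degenerate meshes fail loudly: near-isotropic meshes have no principal
  axis, collinear point sets cannot be registered, an empty curvature region
  reports a threshold advisory.
* The wrist-angle zero for PS depends on styloid anatomy; absolute
  ulnoradial angles therefore carry a per-wrist offset on real data, while
  delta values and ranges are offset-free.

## Problem sizes

Validation runs at desk scale, chosen to exercise every code path while
keeping the full suite in minutes: phantom meshes of roughly 1,500–2,500
vertices per bone, 11 frames per sequence, 30 wrists per movement for the
recovery study, 100 seeded instances for landmark robustness and
registration trials. All randomness is seeded; two identical runs produce
byte-identical CSV output.
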