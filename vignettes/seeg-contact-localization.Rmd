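---
title: "Localizing SEEG depth-electrode contacts in post-implant CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing SEEG depth-electrode contacts in post-implant CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stereo-EEG (SEEG) implants carry ten to twenty depth electrodes, each a thin
shaft with 5–18 cylindrical platinum–iridium contacts (2 mm long, 0.8 mm in
diameter, separated by a 1.5 mm gap, i.e. a centre-to-centre pitch of
d = 3.5 mm). Interpreting the recorded local field potentials requires
knowing where every contact sits in the patient's head. Manually clicking
hundreds of contact centres in a 3D CT volume takes hours per patient;
`seegloc` automates it in seconds, given

* a post-implant CT volume, ideally bone-subtracted and thresholded
  (`subtract_volumes()`, `apply_threshold()`), and
* the planned entry point E (at the anchoring skull screw) and target point
  T (deepest point) of each electrode, as exported from the planning tool
  (`parse_fiducials()`).

The intensities of cone-beam CT are not calibrated Hounsfield units, so the
method never interprets absolute intensity values: it only distinguishes
metal from background through a single threshold S, either supplied
(clinical practice on the scanner that motivated the method uses 1600) or
chosen automatically as the first genuine local minimum of the image
histogram (`auto_threshold()`).

## The algorithm

All geometry lives in physical millimetres; voxels enter only through the
volume affine, so the anisotropic 0.4 × 0.4 × 0.8 mm grid needs no special
cases. The numeric substrate is the image moment
$M_{pqr} = \sum x^p y^q z^r\, I(x,y,z)$ over an axis-aligned cube and the
centre of mass $(M_{100}, M_{010}, M_{001})/M_{000}$ (`region_moment()`,
`center_of_mass()`). Two primitives are reused everywhere:

* **Growing-cube search** (`find_significant_voxel()`): look for a voxel
  with I > S in a cube of side 3 mm, enlarging by 1 mm up to 10 mm;
  absence is a value (the stop signal), not an error.
* **Centroid refinement** (`refine_centroid()`): iterate the
  centre-of-mass map of a 3 mm cube re-centred at each iterate until two
  consecutive iterates differ by less than ε. Because the centre of mass
  of a fixed voxel set is exact, the iteration reaches an exact fixed
  point once the region's voxel set stops changing — which is why
  reconstructions are bit-reproducible and displacement-invariant rather
  than merely close.

Per electrode the pipeline runs three stages (`segment_implant()`):

1. **Head point H** (`estimate_head()`): the screw masks the most
   superficial contact, but its centre approximates the electrode head
   well. Search a significant voxel around E, refine to the screw
   centroid.
2. **Tip D** (`estimate_tail()`): walk from H toward T in steps of the
   contact pitch d. Each step extrapolates along the line through the two
   previous axis points (the first step uses the H–T line), searches a
   significant voxel near the extrapolated point, and refines it to a
   centroid A_k. The axis is therefore piecewise linear and re-anchors on
   the measured shaft at every step — this is what tracks curved shafts
   and what makes the result independent of target-planning error: the
   planned T only sets the initial direction, and after the first
   successful step the measured shaft takes over. The walk stops on
   signal loss (tip passed), when a candidate fails to advance (the tip
   centroid was re-found), when the hemisphere plane would be crossed, or
   when the walked length exceeds the planned head–target length plus one
   pitch (overshooting farther could only run onto another shaft).
3. **Contacts** (`segment_contacts()`): the same walk, run from D back
   toward H. The first search point lies d/2 from D; since D is itself
   the refined centroid of the deepest contact, the first candidate
   either re-finds that contact (it becomes contact 1) or lands on
   contact 2, in which case D is recorded as contact 1. Contacts are
   numbered 1…N from the tip. The walk stops at the model's contact
   count, on signal loss, at the head region, or when a step lands
   outside 75–125 % of the pitch.

### SEEG-specific corrections

* **Curved shafts** are handled by the piecewise axis itself — no
  separate machinery.
* **Crossing shafts** (`constrained_centroid()`): metal artifact merges
  contacts of nearly-touching shafts into one voxel mass, dragging the
  plain centre of mass off-axis. Electrode geometry bounds the bend
  between consecutive inter-contact segments at 10°; when a refined
  candidate implies a larger bend, the region is shrunk in 0.5 mm steps
  and the refinement repeated until the bend is admissible or the region
  vanishes (the candidate is then flagged as a merged-contact
  diagnostic). The constraint is active whenever both reference points
  are measured; the very first tail step is deliberately unconstrained,
  because its only reference is the planned — possibly displaced — E–T
  line, and correcting toward a wrong plan is exactly what must not
  happen.
* **Bilaterally collinear shafts** (`hemisphere_guard()`): two
  electrodes approaching the same deep target from opposite hemispheres
  can look like one long electrode. No electrode crosses the medial
  longitudinal fissure, so the walk stops as soon as a candidate's
  signed distance to the fissure plane changes sign relative to the head
  point. The plane defaults to the mid-sagittal plane of the RAS frame
  (x = 0, normal (1,0,0)) and is configurable; computing it from the
  anatomy is outside this package's scope.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| S | auto (1600 clinical) | metal/background intensity cut-off, strict `I > S` |
| search cube | 3 → 10 mm, 1 mm steps | significant-voxel search around E |
| follow cap | 1.5 d = 5.25 mm | cube cap during axis following; keeps the search from leaping to a shaft ≳ 6 mm away while bridging one lost contact |
| region side | 3 mm | centroid-refinement cube: larger than the 2 mm contact, smaller than the 3.5 mm pitch |
| ε | 10⁻³ mm | refinement convergence tolerance (iteration is finitely convergent anyway) |
| max angle | 10° | admissible bend between consecutive segments |
| shrink step | 0.5 mm | region shrink decrement of the crossing correction |
| step d | model pitch (3.5 mm) | axis-following and contact step |
| match tol | d/2 = 1.75 mm | truth-matching tolerance; beyond it a detection is ambiguous between neighbours |

## The synthetic phantom

`make_phantom()` rasterizes an implant specification into a synthetic
post-implant CT: anti-aliased cylindrical contacts (voxel-coverage
supersampling, 4 × 4 × 2 sub-points per anisotropic voxel), a bright
spherical screw blob at each entry, a separable Gaussian metal-artifact
blur (σ = 0.4 mm) that merges nearby contacts, and uniform sub-threshold
background noise. Default intensities are 8000 for contacts and 10000 for
screws against the 1600 threshold. The ratio is deliberately large: a
0.8 mm contact lying between two 0.8 mm CT slices splits its mass across
both, and after blurring its peak intensity falls to roughly a quarter of
nominal; clinically, every implanted contact is visible in CT, so the
generator must keep worst-case partial-volume contacts above threshold.
A consequence worth knowing: the *above-threshold footprint* of a shaft
varies with slice alignment by up to a factor of two even though its
total image mass is conserved — an anisotropic-grid effect, not a
rasterization bug.

Ground truth is the centroid of the blurred, thresholded image mass
assigned to each contact (above-threshold voxels within half a pitch of
the ideal centre and closer to it than to any other metal object), not
the ideal cylinder centre: image mass is all any segmentation can
recover, and this separates rasterization error from algorithm error.

Curved phantom shafts distribute the requested bend over the two joints
flanking the bend contact, as a physical cable does; a full 10° bend
concentrated at a single joint would sit exactly on the method's
admissibility boundary by construction.

What the phantom does **not** emulate: beam-hardening streaks, brain
tissue texture, bone residue from imperfect registration, or electrode
cables. Passing phantom tests therefore demonstrates the geometry engine
and the search logic under realistic voxel and artifact scales — it does
not certify performance on any particular scanner's images.

## The displacement experiment

Planned entry points are reliable (the screw is fixed to the skull), but
targets can deviate by up to tens of millimetres.
`robustness_experiment()` displaces every planned target uniformly on the
circle of a given radius perpendicular to its trajectory (the worst case:
all electrodes displaced at once), re-segments, and reports (i) the paired
per-contact distance to the undisplaced reconstruction — the robustness
error — and (ii) FP/FN rates against ground truth. The two comparisons
answer different questions and are reported separately, with 5th/95th
percentiles per radius.

On the cohort used by `scripts/acceptance.R` (five implants × ten straight
electrodes of 8–18 contacts, radii up to 12 mm, five draws per radius) the
paired error is exactly zero: the displaced initial axis still finds the
shaft at the first step, and from then on the measured geometry drives
the walk to the identical fixed points. At 15 mm a small fraction of
short electrodes can lose the shaft at the first step (the planned
direction misses the superficial contact's search cube) and is counted
as false negatives; spurious detections remain absent.

## Numerical and design choices

* Voxel membership of a region is inclusive of the boundary
  (|coordinate − centre| ≤ l/2 within 10⁻⁹ mm) and regions are clipped at
  the volume border rather than erroring — entry-point search cubes
  routinely touch the skull-side border.
* Threshold comparison is strict: a voxel exactly at S is background.
* Within the first non-empty search cube the significant voxel *nearest
  the cube centre* is taken (ties resolved by column-major voxel order,
  so the choice is deterministic). Selecting by scan order instead would
  make the outcome depend on the shaft's orientation relative to the
  array axes, and near the screw it can seed the refinement inside the
  screw blob, collapsing the first axis step. `order = "lexicographic"`
  is available for the plain scan-order behaviour.
* `auto_threshold()` bins the nonzero intensities into 256 equal-width
  bins, smooths with a 3-bin moving average, and takes the first local
  minimum that dips below half the running maximum — the extra condition
  rejects sampling jitter on a mode's flank, which a bare first-minimum
  rule mistakes for a valley.
* Failures are isolated per electrode: an electrode whose entry or shaft
  cannot be found is reported and skipped; the rest of the implant
  proceeds.
* The algorithm contains no randomness; identical inputs produce
  bitwise-identical outputs. All randomness in this package lives in the
  phantom generator and the displacement draws, both seeded.

## Problem sizes

The phantom grids used throughout the tests and the acceptance script are
190 × 170 × 40 voxels (76 × 68 × 32 mm) for cohort implants and similar
for the special-case phantoms — large enough to hold ten electrodes of up
to 18 contacts with realistic 10–14 mm inter-shaft spacing, small enough
that a full cohort robustness experiment (505 implant segmentations)
runs in about a minute.

## Known limitations

* Entry/target record order in fiducial files is resolved by a
  depth-from-boundary heuristic (`orient_trajectories()`) with explicit
  overrides; a file whose deep point is genuinely closer to the volume
  border than its entry would be mis-oriented.
* The hemisphere plane is a configured geometric plane, not an anatomy
  estimate.
* Electrodes whose most superficial contact lies more than ~6 mm from
  the screw centre break the follow-step reach assumption and will be
  truncated; such cable gaps do not occur in the supported hardware.
* Contacts of shafts closer than about one pitch over several
  consecutive contacts cannot be separated by any centroid-based method;
  the crossing correction handles isolated merged pairs.
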