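---
title: "Assessing the accuracy of CBCT-derived tooth replicas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the accuracy of CBCT-derived tooth replicas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothrep)
```

## The problem

In tooth autotransplantation a donor tooth is extracted and placed into a
prepared recipient site in the same patient. The health of the periodontal
ligament on the root surface decides the outcome, so the donor tooth should
spend as little time as possible outside the socket and should not be
repeatedly test-fitted. A milled physical replica of the donor tooth —
segmented from a cone-beam CT (CBCT) scan and machined from PEEK — lets the
surgeon shape the recipient site against the replica instead of the living
tooth. That is only safe if the replica is an accurate copy.

`toothrep` implements the accuracy-assessment computation for this workflow:

1. **Segmentation** of a CBCT-like volume into a triangulated surface model
   (the *CBCT reconstruction model*),
2. **surface-based rigid registration** of that model (or of a replica
   scan) onto the reference scan of the natural tooth, and
3. **deviation analysis**: per-vertex Euclidean and signed normal distance
   fields, their summary statistics, and blue-to-yellow colour-mapped
   deviation maps.

Real studies of this kind use three physical teeth that cannot be
redistributed. The package therefore ships a **synthetic phantom
generator** whose outputs play the role of the natural teeth: every stage
of the pipeline can be exercised against inputs with exactly known
geometry, which is what the test suite does.

## The phantom generator

A phantom is a parametric implicit solid: a superellipsoid crown,
cusp/ridge bulges, and one or two tapered round-cone roots, blended by a
smooth union of signed distance functions and meshed by isosurface
extraction at a 0.15 mm grid step. Three kinds are provided — premolar and
canine (one root) and a molar whose two roots diverge so that a genuine
furcation saddle exists between them. The cusp and ridge features are not
cosmetic: they break the rotational near-symmetry of a single-rooted
tooth, which is what makes rigid registration a well-posed problem on
these shapes (a perfectly axisymmetric root would leave one rotational
degree of freedom undetermined, for the package exactly as for any
registration software).

The generator emulates, with one tunable each:

* **CBCT voxelisation** (`voxelize`): voxel centres inside the surface get
  `hu_hard_tissue` (default 2000 HU), pulp-canal channels get `hu_canal`
  (300 HU), the background 0 HU; partial-volume averaging is a Gaussian
  blur (`blur_sigma`, default 0.15 mm in the study configuration) and
  detector noise is i.i.d. Gaussian (`noise_sd`, 30 HU). The default HU
  levels straddle the 1600 HU segmentation threshold with dentin-like
  contrast. Voxel spacing defaults to isotropic 0.2 mm, the voxel size of
  high-resolution dental CBCT protocols.
* **Optical scanning** (`perturb_along_normals` inside `run_study`):
  0.01 mm surface noise — stereophotogrammetry scanners are more than an
  order of magnitude more accurate than the CBCT voxel, so the reference
  scan is treated as nearly exact.
* **Milling** (`simulate_replica`): seeded Gaussian displacement along
  vertex normals (0.05 mm) followed by a light Taubin pass, mimicking the
  low-pass character of a rotary tool.
* **Localized defects** (`deform_bump`): a cosine-tapered bump or dent of
  chosen amplitude and support radius, used to inject deviations of known
  size at chosen anatomical sites.

What the generator does **not** emulate: X-ray physics (beam hardening,
scatter, cone-beam artifacts), the adjacent alveolar bone that complicates
root segmentation in vivo, metal restorations, or anatomically accurate
tooth shape. Passing tests therefore demonstrate that the *computational
pipeline* is correct and self-consistent at clinically relevant error
scales — not that any particular scanner or mill meets a specification.

### One systematic effect worth knowing about

Thresholding at 1600 HU is *not* at the midpoint of the 0–2000 HU edge
profile. After partial-volume blur the recovered surface therefore sits
slightly inside the true surface (by about 0.85 blur sigmas, roughly
0.13 mm at the defaults). This is faithful to real CBCT segmentation at a
fixed calibrated threshold, and it is why the synthetic study reports mean
deviations around 0.15 mm rather than zero even though every individual
algorithm is exact to well below a voxel. The noise-free fidelity checks
(`analysis/02_segmentation_fidelity.R`) disable blur and show the
remaining discretisation error is about half a voxel.

## Segmentation

`segment_volume` composes four steps, each exported on its own:

* `threshold_volume` — foreground is `value > 1600` with a **strict**
  inequality, stated explicitly because synthetic volumes contain voxels
  exactly at the threshold.
* `fill_internal_cavities` — pulp canals must not appear in the surface
  model. Enclosed cavities are found by flood-filling the background from
  the grid boundary (6-connectivity against 26-connected foreground, the
  standard complementary pair). Canals that open at the apex are caught by
  a second pass: the mask is closed with a digital ball (radius 3 voxels)
  *only to detect* the then-enclosed cavity; the closing itself is never
  written to the output, so the outer surface is untouched and the
  furcation region is not artificially rounded. The operation is
  extensive and idempotent.
* `largest_component` — suppresses noise speckle; ties broken by lowest
  linear voxel index.
* `extract_surface` — isosurface at level 0.5 of the binary mask.

Isosurfaces are extracted by **marching tetrahedra** (each grid cube split
into six tetrahedra sharing the main diagonal). This variant was chosen
over classic table-driven marching cubes because it is watertight by
construction, orientable per tetrahedron, and verifiable without trusting
a 256-case lookup table; its output is welded exactly through edge-keyed
vertex sharing. On a raw binary mask any isosurface is a staircase whose
area overestimates a smooth surface by several percent, so
`extract_surface` first smooths the mask with a small Gaussian
(`smooth_sigma_voxels = 0.8`); this sub-voxel anti-aliasing brings sphere
area and volume errors below one percent while staying on the
threshold-then-surface route. Setting the sigma to 0 recovers the raw
blocky surface.

## Registration

`best_rigid` is the closed-form weighted least-squares fit of a proper
rigid transform (SVD of the covariance with determinant correction, no
scaling); degenerate (collinear) configurations are an error.

`initial_align` aligns area-weighted centroids and principal axes. The
weighting matters: vertex *density* of extracted meshes is anisotropic
(the tetrahedral decomposition has a preferred diagonal), so unweighted
vertex covariance would misestimate the axes. The four proper sign
combinations are scored by sampled closest-point RMS; near-isotropic
shapes (eigenvalue spread under 20%) fall back to centroid-only
alignment with a message, not an error.

`icp_register` iterates exact point-to-triangle correspondence search
(accelerated by an axis-aligned bounding-box tree; the tree only prunes,
distances are exact), optional trimming, and the closed-form fit. With
exact correspondences and no trimming the RMS history is non-increasing
— the classic ICP guarantee, asserted to 1e-9 in the tests. Because
point-to-point steps converge slowly in the tangential modes of smooth
surfaces, the default configuration switches to linearized
**point-to-plane** polish steps once the point phase stalls (RMS change
below 1e-4 mm); a polish step is accepted only if it does not increase
the point-to-surface RMS, so the monotonicity guarantee survives. On the
phantoms this recovers randomly applied poses (rotations to 20 degrees,
translations to 5 mm) to microdegrees and femtometres; the acceptance
suite requires 0.1 degree / 0.02 mm over 60 seeded trials.

Convergence is judged on the **absolute** RMS change (default 1e-6 mm),
which remains meaningful as the residual approaches zero. Subsampling
(`subsample_count`) is uniform-random with a stored seed and is followed
by a full-vertex refinement pass.

`merge_half_scans` reproduces the two-step optical scanning protocol
(crown scan + root scan combined into a whole-tooth model): ICP with
heavy trimming registers the overlap band, the triangle sets are
unioned, and duplicate vertices are welded at 1e-6 mm. A merge is
refused when fewer than 10% of the moved vertices land within 0.05 mm of
the fixed half.

## Deviation metrics

Both metrics are computed per vertex of a chosen *basis* mesh after
registration:

* **Euclidean distance** — unsigned distance to the closest point
  anywhere on the other surface (point-to-triangle, exact). It can be
  deflated by tangential mismatch: a protrusion of height $a$ on the
  other surface yields a closest-point distance below $a$ whenever the
  rim of the protrusion is nearer than its peak.
* **Normal distance** — a ray is cast from each vertex along its outward
  normal, in both directions; the nearest intersection within
  `max_range` (default 5 mm) gives the magnitude. The sign convention is
  fixed to the clinical question *"is the natural tooth locally larger
  than the model?"*: positive means yes. `normal_field` reports positive
  when the other surface lies along the outward normal; `compare_models`
  flips the sign when the basis is the natural scan so that the reported
  sign is basis-independent. Vertices with no intersection within range
  are flagged missing and excluded from summaries (the count is
  reported). In deep concavities a normal ray can legitimately cross the
  fissure and hit the opposite wall several millimetres away; such
  values are real geometry, not errors, and they are why signed extremes
  can exceed the Euclidean extremes.

The Euclidean value never exceeds the normal magnitude at any vertex
where both exist — the closest point lower-bounds the distance along any
particular ray — and this inequality is asserted across all phantom
comparisons in the tests.

`summarize_field` reports min, max, mean and median (even counts use the
central-pair mean) over valid values, plus absolute mean and median for
signed fields.

`compare_models` wires the whole comparison together. The basis mesh
follows the study design: deviations of the CBCT reconstruction are
expressed on the *model* mesh, deviations of the replica on the
*natural-tooth scan*.

## The synthetic study

`run_study` executes the full design for each tooth kind: phantom →
natural scan (phantom + localized defect + scanner noise) → CBCT volume
of the defect-free geometry → reconstruction model → simulated replica →
both comparisons. The defect lives only on the natural scan, emulating a
feature the imaging chain failed to capture; its amplitude is therefore
the ground-truth deviation the pipeline should rediscover.

The default defects sit at the anatomical weak spots of CBCT tooth
reproduction: 0.5 mm at the premolar root tip, 1.0 mm on a canine crown
patch (a filling-sized defect), and 1.9 mm in the molar furcation — all
outward, so the expected normal sign is positive. For a tooth's reported
maximum Euclidean deviation we take the larger of its two comparisons:
an outward defect measured *from the model basis* is partially shadowed
by its own rim (the closest-point deflation above), while the
natural-basis comparison sees the full amplitude; the two bases are part
of the study design, so both are computed and the defect recovery is
judged on the tooth, not on one basis. The molar roots are given a wide
divergence so that the furcation notch is open enough for a 1.9 mm
deviation to be geometrically expressible at all — in a narrow notch the
closest surface is always a nearby root wall and no measurement could
return 1.9 mm.

Every stochastic stage draws from a sub-seed derived from the single
study seed, so a config plus seed reproduces every output byte for byte;
the determinism test compares emitted CSVs across two runs.

### Problem sizes

Ground-truth phantoms are meshed at 0.15 mm (60k–90k vertices), volumes
at 0.2 mm spacing (3–5 million voxels), ICP uses 1500–3000 subsampled
correspondences before full-vertex refinement, and the registration
experiment runs 20 trials per tooth kind. These sizes keep the complete
study in the tens of seconds on one core while leaving discretisation
error well below the quantities being measured; the reduced
configurations used in some tests (coarser ground truth, one tooth) are
noted inline where they appear.

## Numerical choices and edge cases

* Strict `>` at the HU threshold; exact-threshold voxels are background.
* 26-connectivity for foreground components, 6 for background flood fill.
* Component ties broken by lowest linear index; median of an even count
  is the central-pair mean; weld tolerance 1e-6 mm.
* Meshes are re-oriented so outward normals enclose positive volume;
  `normal_field` refuses a basis mesh that is not closed and
  consistently wound rather than guessing normals.
* A constant deviation field maps to the mid-ramp colour (not an error);
  missing vertices render neutral grey. The colour ramp endpoints are
  fixed (dark blue `#00008B` to bright yellow `#FFFF00`) so renders are
  reproducible.
* Volumes are stored as int16 raw data plus a JSON header with
  slope/intercept rescaling, mirroring CT rescale semantics
  (`HU = slope * stored + intercept`).

## Known limitations

* The canal-filling morphology (flood fill + ball-closing detection) is
  one reasonable realisation of an operation that clinical packages
  implement in undocumented ways; its closing radius is exposed.
* Point-to-plane polish relies on locally smooth targets; on very coarse
  meshes the polish step may be rejected immediately, leaving the slower
  point-to-point answer (still correct, just fewer digits).
* Deviation statistics are plain vertex statistics; they are not
  area-weighted, so regions of denser tessellation count more. The
  extracted meshes used here are near-uniform, which keeps the
  difference small.
* The normal-distance `max_range` of 5 mm caps how far a ray may search;
  in pathological geometry this turns distant hits into missing values
  rather than reporting spurious correspondences.
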