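---
title: "Methods: vesicle morphometrics, helical lattice geometry and plasticity metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vesicle morphometrics, helical lattice geometry and plasticity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodmorph)
```

`rodmorph` bundles the quantitative procedures used to characterize
membrane remodelling by helical ESCRT-III-family polymers such as PspA:
morphometrics of vesicle fields from segmentation masks, rod diameter and
lattice arithmetic from helical symmetry parameters, conformational
plasticity metrics on atomic models, and the supporting ATPase assay
statistics. This vignette explains the underlying models, the parameters
that matter, the numerical choices made where the procedures leave room,
and what the synthetic validation data do and do not establish.

## Vesicle morphometrics

### Model

A micrograph segmentation is a binary mask in which each membrane appears
as a thick closed band. The analysis reduces each band to its one-pixel
skeleton, treats the skeleton as the membrane's mid-line, and derives all
per-vesicle quantities from it:

- **Perimeter**: the sum of Euclidean distances between consecutive
  skeleton points (including the closing segment), scaled by the pixel
  size and reported in nm. The equivalent circular diameter is
  `perimeter / pi`.
- **Nesting**: vesicle A is enclosed by vesicle B when A's skeleton points
  lie inside the closed polygon of B's trace (even-odd rule). A vesicle
  enclosed by at least one other vesicle is a double-membrane vesicle; the
  double-membrane fraction uses all closed vesicles as denominator.
- **Enclosure distance**: the minimum Euclidean distance between the two
  skeletons, in Å.
- **Bilayer thickness**: image intensities are sampled along the local
  normal at every skeleton point, averaged over the trace, and the
  distance between the two deepest local minima of the averaged profile
  (the two leaflets, which are dark in cryo-EM contrast) is the thickness.

### Numerical choices

**Skeletonization** uses Zhang–Suen morphological thinning, applied per
connected component inside its bounding box so cost scales with membrane
area. Components are labelled with 8-connectivity (an in-package labeller
built on graph components; 4-connected labelling would fragment thin
diagonal structures). Skeleton pixels are ordered into a trace by walking
an m-adjacency graph — 8-adjacency with redundant diagonal edges removed —
under which a unit-wide curve has vertex degree ≤ 2. Components containing
junction pixels (degree ≥ 3) beyond `max_branch_nodes` (default 0) are
discarded and counted: they correspond to aggregated or overlapping
membranes whose tracing is ambiguous. Only closed traces (no endpoints,
first and last points adjacent) enter the vesicle analysis.

**Perimeter debiasing.** Summing raw pixel-centre steps overestimates the
length of a smooth digitized curve by 5–10 % (the staircase of 1 and
√2 steps). `vesicle_perimeter()` therefore applies a circular moving
average (default 5 points) to the ordered trace before summing. The window
subtends a tiny arc on any realistic vesicle, so the induced radial shrink
is negligible (below 0.1 %), while the staircase noise cancels. Traces
shorter than three window widths are summed raw so that tiny hand-made
polygons are measured exactly.

**Containment rule.** Strict containment (all points inside) is the
default; a `"majority"` rule (more than half of the points) is available
for masks with marginal overlaps. Containment relations between distinct
closed skeletons cannot be mutual, and a cycle check guards against
inconsistent inputs.

**Thickness estimation.** The local normal at a skeleton point is
perpendicular to the secant through the points ±k positions away (default
k = 3, cyclic on closed traces); profiles are sampled by bilinear
interpolation at 0.5 px steps over ±`half_width_A` (default 60 Å). Minima
positions are refined with a three-point parabola (vertex clamped to half
a grid step) before taking their separation. Results outside the plausible
window (default 20–100 Å) or profiles with fewer than two local minima
yield `NA` rather than a number; traces closer to the image border than
the sampling half-width are an error, not a silent truncation.

### Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `pixel_size` | 7 | Å/px | segmentation scale |
| `max_branch_nodes` | 0 | junction px | ambiguity cut-off |
| `min_points` | 8 | px | minimum skeleton length |
| `smooth_window` | 5 | points | perimeter staircase debiasing |
| `half_width_A` | 60 | Å | normal sampling half-width |
| `thickness_window_A` | 20–100 | Å | plausible bilayer separations |
| `secant_k` | 3 | points | tangent estimation |

The plausible-thickness window spans the single- and stacked-bilayer
separations observed in liposome cryo-EM (roughly 27–68 Å) with margin on
both sides. The minimum vesicle size and the aggregation cut-off are
deliberately configuration knobs: no principled universal values exist for
them.

## Rod geometry from radial profiles

A rotationally (for 3D maps, cylindrically) averaged intensity profile is
normalized to a maximum of 1. The rod radius is read where the profile
falls through a cutoff of 0.3; the **outermost** falling-edge crossing is
used, with linear interpolation between grid points, so luminal density
inside wide "super rods" cannot shrink the measured diameter — the
diameter describes the outer wall. Radii of profiles from the same
symmetry class may be averaged before conversion. Diameters are rounded
half-up to the nearest 5 Å, matching the diameter-class convention.
Leaflet radii of engulfed membrane tubes are the two highest local maxima
of the same profile, parabola-refined.

## Helical lattice arithmetic

A helical lattice is the screw operation (rise in Å, twist in degrees)
plus an n-fold cyclic symmetry. Derived quantities are pure arithmetic:

- per-asymmetric-unit rise: `rise / n`;
- mass-per-length: `n · monomer_mass / rise` (kDa/Å), with the identity
  `MPL · rise / n = monomer_mass` holding for all inputs;
- monomer count of a rod of length L µm: `1e4 · L · n / rise`, linear in
  L, optionally rounded to a significant-figure level for
  order-of-magnitude reporting;
- lattice neighbours: the subunit at k helical steps and c cyclic copies
  sits at azimuth `k·twist + c·360/n` and height `k·rise`; its distance
  from the reference on the cylinder of radius R combines the chord
  `2R sin(Δφ/2)` with the axial offset. `neighbor_offsets()` reports all
  offsets within `±k_max`, ranked by distance, rather than asserting
  specific pocket indices — the chain-numbering convention that makes a
  particular binding pocket come out as specific offsets is
  deposition-dependent. Chain indexing is helical-step-major,
  cyclic-copy-minor.

The package ships the eleven ATP-condition rod classes (180–365 Å) as a
CSV (`pspa_symmetry_table()`), from which the per-subunit rise decrease
and the near-perfect linearity of mass-per-length versus diameter are
recomputed, not hard-coded.

## Structural plasticity metrics

**Superposition** is the orthogonal Procrustes solution via SVD (Kabsch):
the proper rotation (determinant +1 enforced by sign correction of the
smallest singular direction) and translation minimizing RMSD. Collinear
point sets (second singular value numerically zero) are rejected as
degenerate rather than silently resolved.

**Hinge displacement angles.** Each hinge is defined by a pivot range and
the two flanking helical segments. After superposing query on reference
over the hairpin, the displacement at a hinge is the change (query minus
reference) of the signed opening angle between the principal axes of the
proximal and distal segments. Two properties motivated measuring between
flanking segments rather than against the global frame: the three hinges
become independent (a rotation at one hinge rigidly carries everything
downstream, which in a global-frame reading would masquerade as equal
displacement at all later hinges), and the sign is intrinsic, giving exact
antisymmetry between query and reference. The opening angles are signed
against the bisector of the two hinge-plane normals; this convention
degenerates only when the two hinge planes are nearly opposite, far
outside the deformations of interest. Principal axes are oriented from the
segment's first toward its last residue. Default ranges place hinge 1 at
the α2/α3 transition (pivot 128–133), hinge 2 at the α3/α4 loop (156–165)
and hinge 3 at the α4/α5 loop (187–189); the helix boundaries are
approximations and fully overridable, as the true boundaries shift between
rod classes.

**Contacts.** For residue pairs on neighbouring chains, Cα distances are
measured in each model of a diameter-ordered series; changes are taken
relative to the first (smallest-diameter) class, and their standard
deviation — population form by default, sample form switchable, since the
convention is not canonical — classifies the pair: below 1 Å the contact
is fixed, above it the contact switches partners as the diameter changes.
The s.d. deliberately measures the *variance* of change, not its
magnitude: a pair offset by a constant in every class is still fixed. The
conserved-pair list is configuration input, not computed.

**Helical extent** scans a residue range for stretches whose Cα(i)→Cα(i+4)
distance lies within 5.9–6.7 Å, the i,i+4 spacing band of an ideal
α-helix (rise 1.5 Å, twist 100°, radius 2.3 Å gives 6.2 Å); maximal runs
are reported, which captures the growth of the α3/α4 helix as the
connecting loop vanishes in wider rods.

## Activity statistics

ATPase activity is `Δ[P_i] / ([Protein] · Δt)` in h⁻¹. Phosphate standard
curves are ordinary least squares of absorbance on concentration; unknowns
are inverted after subtracting the assay background. Group comparisons use
the two-sided two-sample t-test in Welch's unequal-variance form — chosen
because assay groups have unequal sizes and no variance-homogeneity
guarantee; the pooled form is switchable. Group summaries follow the
boxplot convention of mean ± s.e.m. (sample s.d. over √n), 10th/90th
percentiles as whiskers (linear-interpolation quantiles, R type 7) and
values outside the whiskers as outliers. Relative activities are ratios of
group means; computing per-replicate ratios first is a defensible
alternative the package does not take, because replicate pairing across
groups is not generally defined.

## The synthetic-data generator

The generator is the validation backbone and defines the conditions under
which the estimators are tested.

**Vesicle fields.** Vesicles are circles (optionally perturbed by a
low-order Fourier contour term) rendered as two Gaussian dark rings
(σ = 1 px) at ±spacing/2 around the mid-radius on a zero-mean background
with optional Gaussian noise; the mask is the union of the membrane
annuli. Defaults mirror liposome cryo-EM practice: 7 Å/px segmentation
scale, mid-radii of 20–46 px (perimeters of roughly 90–200 nm), bilayer
spacings of 28–40 Å, and enclosure gaps of 58–76 Å for nested vesicles.
Placement is rejection sampling with a retry cap (default 1000) and a
placement-failure error beyond it; non-nested vesicles may not overlap,
and nested children keep a rasterization-safe clearance from their parent
(annulus separation above the pixel diagonal) so each vesicle is exactly
one 8-connected mask component. Ground truth records the analytic
perimeter (dense polygonal integration of the true contour), parent links
and the numerically exact minimum contour separation. Identical
parameters and seed reproduce a field bit-identically; the generator's
RNG use is isolated from the caller's stream.

What the fields do **not** emulate: electron-optics effects (CTF, dose),
segmentation errors (broken or merged bands, false positives),
non-circular vesicle shapes beyond smooth Fourier perturbation, and
membrane contrast variation along a vesicle. Passing the recovery tests
therefore establishes the correctness of the geometry pipeline on clean
segmentations, not robustness to segmentation failure — on real data the
mask quality is inherited from the upstream segmentation model.

**Radial profiles** are a plateau with a logistic edge (width `falloff`;
0 gives an ideal step) optionally carrying two Gaussian leaflet peaks,
plus seeded noise. A 0.3 cutoff on a logistic edge reads ≈ 0.85·falloff
outside the nominal radius, so narrow edges (≲ 2 Å) keep 5 Å rounding on
the correct class; the demo pipeline uses 0.8 Å.

**Toy monomer and assemblies.** The 200-residue hairpin-like Cα trace
(residues 22–221, ideal helical segments joined by straight loops, with a
segment map mimicking PspA numbering) is explicitly *not* the real fold —
it exists so that superposition, hinge and contact analyses can be tested
against constructed rigid transformations. `perturb_monomer()` is the
forward model for hinge recovery; `generate_helical_assembly()` applies
the screw operation exactly, so intra-chain distances are preserved to
machine precision and 30 steps of a C2 symmetry reproduce the 60-monomer
assemblies used in model refinement.

## Problem sizes and tolerances

The test suite exercises: fields of 60 noiseless and 200 noisy vesicles
(membrane contrast-to-noise 5) for perimeter (< 5 % of analytic truth),
nesting (exact), enclosure distance (< 2 px·pixel size) and
double-membrane fraction (exact noiseless, binomial 95 % CI noisy);
thickness recovery over 20–80 Å spacings at 1–7 Å/px (mean absolute error
below max(1 Å, 0.5 px·pixel size)); hinge-angle recovery of ±5–45°
injections within 0.5°; superposition against 1000 random rigid
placements; and t-test type-I calibration (2000 null replicates,
Kolmogorov–Smirnov at α = 0.01). These sizes were chosen as the smallest
that make the statistical checks meaningful.

## Known limitations

- The skeleton mid-line underestimates the perimeter of very small
  vesicles (mid-radius ≲ 10 px) where the annulus is thick relative to
  its radius.
- Bilayer thickness becomes biased low when the leaflet separation
  approaches the ring width in pixels (e.g. 20 Å at 7 Å/px), as the two
  intensity dips begin to merge.
- Hinge angles require the flanking segments to be genuinely helical; the
  principal axis of a partially unfolded segment is unstable, and ranges
  should then be adjusted.
- `contact_series()` indexes chains positionally; models in a series must
  be built with consistent chain order.
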