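# rodmorph

Quantitative morphometrics for cryo-EM studies of membrane-remodelling
ESCRT-III-family proteins such as the bacterial phage shock protein A
(PspA). PspA self-assembles into helical rods of variable diameter that
engulf and remodel lipid membranes; characterizing that plasticity requires
a set of small, well-defined measurements that recur across such studies.
`rodmorph` implements them as composable, tested R functions:

- **Vesicle morphometrics** from binary membrane segmentations:
  skeletonization (Zhang–Suen thinning), closed-vesicle selection,
  perimeter (sum of neighbour distances along the skeleton, staircase
  debiased), nesting/enclosure detection (point-in-polygon), enclosure
  distance, and bilayer thickness from the distance between the two minima
  of the radially averaged membrane intensity profile.
- **Rod geometry** from radial intensity profiles: diameter at an intensity
  cutoff of 0.3 with 5 Å rounding, and leaflet radii at the profile peak
  maxima.
- **Helical lattice arithmetic** from rise/twist/Cn symmetry: per-subunit
  rise `rise/n`, mass-per-length `n·m/rise` (kDa/Å), monomer counts per rod
  length, ranked lattice-neighbour offsets on the cylinder, and local
  turnover amplification.
- **Structural plasticity** on atomic models: least-squares (Kabsch)
  superposition, hinge displacement angles measured as the change in the
  signed opening angle between the helices flanking each hinge,
  Cα82–Cα187 end-to-end ("bow") distance, helical-extent scanning, and
  fixed-versus-switching classification of inter-subunit contacts by the
  standard deviation of their Cα-distance changes across rod classes
  (threshold 1 Å).
- **ATPase activity statistics**: activity `Δ[P_i]/([Protein]·Δt)` in h⁻¹,
  phosphate standard-curve regression and inversion, relative activity,
  Welch's two-sided two-sample t-test, and boxplot-convention group
  summaries (mean ± s.e.m., 10–90th percentile whiskers, outliers).
- A **seeded synthetic-data generator** producing vesicle fields with exact
  analytic ground truth, rod radial profiles of known radius, and idealized
  helical assemblies from a toy monomer — the validation backbone for all
  of the above.

Everything takes plain data or tidy tables and returns tibbles, so results
chain with the pipe; `plot_*()` helpers produce ggplot2 figures, and fitted
objects have `tidy()`/`glance()` methods.

## Worked example

Generate a small vesicle field with known ground truth, measure it, and
summarize:

```r
library(rodmorph)

field <- generate_vesicle_field(n_vesicles = 60, nested_fraction = 0.25,
                                seed = 101)
vesicles <- measure_vesicles(field$mask, field$pixel_size)
summarize_vesicles(vesicles)
#> # A tibble: 1 × 7
#>       n mean_perimeter_nm mean_diameter_nm mean_thickness_A n_thickness
#>   <int>             <dbl>            <dbl>            <dbl>       <int>
#> 1    60              124.             39.3               NA           0
#> # ℹ 2 more variables: mean_enclosure_distance_A <dbl> (63.3),
#> #   double_membrane_fraction <dbl> (0.25)
```

Sixty vesicles with a mean perimeter of about 124 nm (mean equivalent
diameter `perimeter/π` ≈ 39 nm) and a mean enclosure distance of 63 Å
between nested membranes; a quarter of them were constructed nested,
and `double_membrane_fraction` recovers exactly 0.25. A vesicle population
with a mean perimeter of 100 nm corresponds to a mean diameter of 32 nm.

Lattice arithmetic for the rod classes (rise/twist/Cn per diameter):

```r
pspa_symmetry_table()
#> # A tibble: 11 × 6
#>    diameter_A cyclic_n rise_A twist_deg rise_per_asu_A mass_per_length_kDa_A
#>         <int>    <int>  <dbl>     <dbl>          <dbl>                 <dbl>
#>  1        180        1   3.18    -161.            3.18                  7.96
#>  2        200        2   5.75      34.4           2.88                  8.8
#>  3        215        1   2.52     130.            2.52                 10.0
#>  # … 8 more rows

monomer_count(2.6, helical_symmetry(1, 2.52, 130.2), signif_digits = 1)
#> [1] 10000
local_turnover(3, 1000)
#> # A tibble: 1 × 2
#>   rate_per_h rate_per_min
#> 1       3000           50
```

A 2.6 µm rod of the 215 Å class holds roughly ten thousand monomers; if
only a thousandth of its sites hydrolyse ATP at a given moment, a 3 h⁻¹
bulk rate corresponds to a local turnover of 3000 h⁻¹, i.e. 50 ATP per
minute.

Hinge-angle recovery on a constructed conformer:

```r
ref <- toy_monomer()
query <- perturb_monomer(ref, hinge = 160, angle = 20, axis = c(0, 1, 0))
hinge_angles(query, ref)
#> # A tibble: 3 × 5
#>   hinge  angle_deg opening_query_deg opening_reference_deg rmsd_hairpin_A
#> 1 hinge1      0                  1.75                  1.75             0
#> 2 hinge2    -20.0               14.4                  34.4              0
#> 3 hinge3      0                 31.1                  31.1              0
```

The injected 20° rotation at the α3/α4 loop is recovered at hinge 2 and
leaves the other two hinges untouched.

## Scope

The package starts from segmentation masks, maps/profiles, atomic models
and measurement tables. Upstream steps of a cryo-EM workflow — movie
processing, classification, helical refinement, neural-network
segmentation, model building — are out of scope.
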