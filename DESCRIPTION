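Package: rodmorph
Title: Quantitative Morphometrics of Membrane Vesicles and Helical Protein Rods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification tools for cryo-EM studies of membrane-remodelling
    ESCRT-III-family proteins such as bacterial PspA. Implements vesicle
    morphometrics from binary membrane segmentations (skeletonization, closed
    vesicle selection, perimeter, nesting and enclosure distance, bilayer
    thickness from radially averaged intensity minima), rod diameter
    measurement from radial intensity profiles, helical lattice arithmetic
    from rise/twist/cyclic symmetry (per-subunit rise, mass-per-length,
    monomer counts, lattice neighbour offsets), structural plasticity metrics
    on atomic models (least-squares superposition, hinge displacement angles,
    end-to-end distances, fixed versus switching contact classification), and
    ATPase activity statistics with the associated standard-curve and
    group-summary conventions. A seeded synthetic data generator provides
    vesicle fields, radial profiles and idealized helical assemblies with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    igraph,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
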