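Package: invasionmap
Title: Trajectory-Based Mapping of Tumor Invasion from Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds per-voxel maps of microstructural change around a brain
    tumor from co-registered diffusion MRI volumes. Given a white-matter
    mask, a tumor mask, a diffusion-tensor field and one or more scalar
    parametric maps (e.g. diffusion-kurtosis metrics), the package labels
    white matter by step distance to the tumor border, builds
    tensor-weighted random-walk transition matrices on the voxel lattice,
    generates pseudorandom trajectories from distant white matter to the
    tumor margin, extracts and median-smooths parametric profiles along
    them, detects significant rising and falling gradient segments, and
    aggregates these into percentage maps (100*P/Q) of trajectories showing
    a significant gradient at each voxel. A synthetic phantom generator
    with planted ground truth supports end-to-end testing without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
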