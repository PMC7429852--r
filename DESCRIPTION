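Package: trabstrain
Title: Sub-Trabecular Strain Analysis by Local Digital Volume Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Local digital volume correlation (DVC) on sequences of 3D
    tomographic images of trabecular bone under stepwise compression.
    Provides zero-normalized cross-correlation block matching with
    tri-quadratic and gradient-based sub-voxel refinement, displacement
    outlier/median filtering, Green-Lagrange strain tensors on 8-node
    hexahedral elements, volumetric strain det(F)-1, automated crack
    segmentation by dual-threshold binary morphology, crack versus
    non-crack cumulative strain statistics, a voxel-size downscaling
    study, virtual-shift accuracy/precision validation, bulk compressive
    mechanics (apparent modulus, 0.2 percent offset yield, toughness),
    and trabecular morphometry (BV/TV, local thickness, tissue mineral
    density calibration). A synthetic trabecular-phantom generator with
    known displacement fields, cracks and load curves makes every stage
    testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    graphics,
    tiff,
    pracma
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
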