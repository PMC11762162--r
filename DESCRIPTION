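Package: odontometry
Title: Automated Tooth-Size and Arch-Width Measurement from CBCT Volumes and
    Colored Model Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An automated pipeline for odontometry: mesio-distal tooth widths
    and maxillary arch widths measured from cone-beam computed tomography
    (CBCT)-like voxel volumes and from colored surface scans of plaster dental
    models. Separates upper from lower teeth in 3D by fusing per-slice
    segmentation with a panoramic reprojection along the fitted dental arch
    curve, classifies scan points into teeth and gum with a fixed-radius
    nearest-neighbor gravitational color classifier, identifies individual
    teeth on maximum-intensity projections with an adaptively estimated jaw
    midline, locates mesial and distal landmarks with a coarse-to-fine
    cascade, and lifts them to 3D through axial depth maps. Ships a synthetic
    dental-phantom generator with full ground truth so every stage is testable
    without clinical data, and the agreement statistics (ICC, one-way ANOVA,
    Bland-Altman limits, success-rate curves) used to validate such pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    grDevices,
    tibble,
    dplyr,
    generics,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
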