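Package: trabmorph
Title: Trabecular Bone Morphometry from Multimodal CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for three-dimensional trabecular bone microstructure
    analysis from computed tomography volumes. Reads and writes volumes with
    anisotropic voxel spacing (NIfTI, MetaImage, TIFF stacks), segments bone by
    Otsu thresholding or an automated region-growing algorithm, thins masks to
    topology-preserving skeletons, and computes the standard structure
    parameters: bone volume fraction (BVTV), trabecular thickness (Tb.Th),
    separation (Tb.Sp), spacing (Tb.Sc), node density (Tb.Nd), the intra-volume
    dispersions s(Tb.Th), s(Tb.Sp), s(Tb.Sc), and contrast-to-noise ratio
    (CNR). A synthetic-specimen generator and a scanner simulator emulating
    micro-CT-, photon-counting-CT- and energy-integrating-CT-like acquisitions
    support validation and modality comparison with median/IQR summaries,
    over/underestimation factors and Spearman rank correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tiff,
    yaml,
    jsonlite,
    withr,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
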