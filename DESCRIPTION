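Package: pepatlas
Title: Single-Cell Neuropeptide Atlases from Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds single-cell resolution neuropeptide atlases of small
    invertebrate nervous tissue from MALDI mass spectrometry imaging (MSI).
    Reads and writes imzML/ibd pixel spectra, TIC-normalizes them and extracts
    per-peptide ion images; registers the 20-micron MSI grid onto co-acquired
    fluorescence microscopy of peptidergic cells by a rigid transform with
    bilinear resampling; masks the resampled ion images to segmented cells to
    produce per-peptide mapping images; quantifies pairwise peptide
    colocalization over serial-section stacks with pixel-area Tanimoto and
    Manders coefficients (intermodes or fixed-range binarization); and
    assembles registered section stacks into 3D volumes exported as STL
    surface meshes. A synthetic ganglion-phantom generator provides
    co-registered microscopy images and imzML datasets with known cells,
    regional expression programs and transforms as ground truth for every
    stage. Peptide bookkeeping includes monoisotopic mass and b/y fragment-ion
    arithmetic with ppm-tolerance matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    xml2,
    pheatmap,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    digest,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
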