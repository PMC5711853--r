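Package: canopyvi
Title: RGB and Multispectral Vegetation Indices for Plot-Based Field Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts colour-based vegetation indices (HSI hue, CIELab, CIELuv,
    Green Area and Greener Area canopy-cover fractions) from plot RGB images and
    the standard broadband and narrow-band multispectral indices (NDVI, SAVI,
    OSAVI, RDVI, EVI, PRI, MCARI, TCARI, ARI2, CRI2, WBI) from co-registered
    reflectance band stacks. Emulates the resolution difference between ground
    and aerial (UAV) acquisition by block-mean downsampling, generates synthetic
    two-treatment canopy trials with known ground truth for validation, and
    provides the statistical layer used in early-vigour yield studies: treatment
    ANOVA, grouped Pearson correlation tables, forward stepwise regression with
    per-term variance portions, and isotope delta notation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
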