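Package: oxiquant
Title: Site-Specific Protein Oxidation, Phosphohistidine Phosphatase
    Activity, and Enzyme Kinetics from Mass-Spectrometric and
    Colorimetric Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative analysis of reactive-oxygen-species-driven
    protein oxidation and its functional consequences, built around the
    125-residue phosphohistidine phosphatase PHPT1 but applicable to any
    peptide-level workflow. Provides deterministic peptide chemistry
    (monoisotopic and average masses, modifications, H+/Na+/K+ adduct m/z,
    b/y fragment ions with phosphate and methionine-sulfoxide neutral
    losses, in-silico tryptic digestion); extracted-ion-chromatogram (XIC)
    quantitation of oxidation stoichiometry at ppm mass tolerance with
    fold changes and t-tests; a direct-infusion phosphohistidine
    phosphatase activity analysis with time-window spectral averaging and
    adduct-summed phospho ratios; per-residue conformational-ensemble
    discriminability via cross-validated linear classification after
    least-squares superposition; and Michaelis-Menten kinetics from
    colorimetric pNPP progress curves with Beer-Lambert conversion.
    Synthetic-data generators with recorded ground truth accompany every
    analysis stage, so each estimator can be exercised against known
    answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    bio3d,
    optparse,
    Biostrings,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
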