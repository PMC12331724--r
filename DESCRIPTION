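Package: ClearQuant
Title: Depth-Resolved Signal-Intensity Quantification for Tissue Optical Clearing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well optical-clearing protocols preserve multiphoton
    autofluorescence and second-harmonic-generation signal at depth. Extracts
    per-slice mean-intensity profiles from z-stacks, normalizes depth and
    intensity, smooths each profile with reproducing-kernel (meshfree) shape
    functions evaluated on a fixed normalized-depth grid, summarizes
    transparency as the area under the normalized intensity curve, and compares
    groups with factorial ANOVA or the aligned rank transform. Includes a
    Beer-Lambert synthetic z-stack generator with hierarchical specimen/region
    variability for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tiff, yaml, car
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'stack-io.R'
    'rk.R'
    'auc.R'
    'profiles.R'
    'synthetic.R'
    'stats.R'
    'pipeline.R'
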