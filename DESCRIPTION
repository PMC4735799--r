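Package: egfrswitch
Title: EGFR Ligand-Switching Signal Strength and Cell Clustering Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how switching between the EGFR ligands EGF and
    amphiregulin (AREG) alters receptor-level signal strength and epithelial
    phenotype. Provides a mass-action ordinary differential equation model of
    EGFR binding, phosphorylation, trafficking, degradation and synthesis in
    which the two ligands differ only in dissociation affinity; hybrid
    parameter estimation by self-adaptive (meta) evolutionary programming
    followed by Nelder-Mead refinement over independent restarts; integrated
    signal strength (area under the curve) quantification of phospho-protein
    time courses including ERK re-activation onset detection; the
    nucleus-nucleus distance index for quantifying cell clustering in
    nuclei-stained micrographs (Otsu threshold, fill-hole, opening, five-pixel
    dilation, object counting); and synthetic-data generators with known
    ground truth for both densitometry time courses and nuclei images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    jsonlite,
    png,
    tiff,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
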