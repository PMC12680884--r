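Package: aifrag
Title: CID Fragment Annotation for Full MS/AIF Data-Independent LC-HRMS
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates collision-induced dissociation (CID) fragments in
    data-independent all-ion-fragmentation (full MS/AIF) LC-HRMS runs of
    complex mixtures such as organic aerosol extracts.  Given a centroided
    mzML file with alternating full-MS and AIF scans and a peak list of
    precursor ions (m/z, retention time), the package predicts precursor
    and fragment molecular formulas by isotopologue-pattern scoring, links
    fragments to precursors by the area between their normalized extracted
    ion chromatograms together with a subformula constraint, computes
    neutral losses, and reconstructs quasi-isolated MS2 spectra.  A seeded
    simulator generates full MS/AIF runs with known ground truth for
    validation, and summary utilities report Van Krevelen coordinates and
    carbon oxidation states of annotated compounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mzR,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
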