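Package: eims
Title: Evaluation Toolkit for In Silico Electron Ionization Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to judge predicted 70 eV electron ionization (EI) mass
    spectra against reference libraries: reading, writing, unit-mass binning
    and normalization of spectra in JCAMP-DX and NIST MSP text formats;
    cosine and mass-weighted dot-product match factors on the 0-1000 scale;
    assembly of consensus spectra from trajectory fragmentation events with
    ionization-potential-based charge assignment (Stevenson's rule);
    molecular flexibility descriptors (rotatable bond number and the Kier
    flexibility index) from hydrogen-suppressed molecular graphs; and batch
    evaluation statistics including score-threshold fractions, compound-class
    comparisons and flexibility correlations. A seeded synthetic-data
    generator emulates the characteristic error modes of quantum-chemistry
    spectrum prediction so the whole pipeline is testable without external
    reference libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
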