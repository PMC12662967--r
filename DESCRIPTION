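Package: acidome
Title: Proteome Acidity Analysis Under Carbonate Chemistry Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study proteome-wide isoelectric point (pI) tuning in
    marine organisms exposed to changing seawater carbonate chemistry.
    Computes protein net charge and pI from sequence under selectable pKa
    scales, quantifies acidity shifts between up- and down-regulated
    proteins in label-free differential abundance experiments (Fisher exact
    and permutation tests on pI distributions), correlates residue-class-rich
    protein abundance with seawater chemistry, speciates the seawater
    carbonate system (CO2, bicarbonate, carbonate, DIC, buffer capacity) from
    total alkalinity and pH, compares genome-encoded proteome pI
    distributions across species, and simulates complete experiments with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
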