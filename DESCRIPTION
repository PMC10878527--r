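Package: vegfrtraffic
Title: Mechanistic Model of VEGFR1, VEGFR2 and NRP1 Trafficking in Endothelial Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mass-action ordinary-differential-equation model of the expression,
    dimerization and subcellular trafficking of the VEGF receptors VEGFR1 and
    VEGFR2 and the co-receptor Neuropilin-1 (NRP1) in human endothelial cells.
    The model tracks receptors and receptor complexes on the cell surface, in
    Rab4a/5a early endosomes and in Rab11a recycling endosomes, with constant
    receptor synthesis, first-order internalization, recycling, inter-endosomal
    transfer and degradation, and reversible receptor-receptor coupling scaled
    by compartment membrane area. Includes protocol simulation of perturbation
    experiments (cycloheximide chase, chloroquine, Rab4a/Rab11a siRNA
    knockdown), multistart bounded Levenberg-Marquardt calibration with an
    inner production-rate solve, local and global sensitivity analysis,
    transport-rate and flux-balance analysis, closed-form dimerization
    equilibria, and a synthetic pseudo-western data generator for
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
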