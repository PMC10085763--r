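Package: rcgs
Title: Rapid-Cycle Recurrent Genomic Selection: Simulation, Prediction and Gain Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying rapid-cycle recurrent genomic selection (RCRGS) in
    self-pollinated crops such as spring bread wheat. Provides a forward simulator of
    bi-parental breeding populations (meiosis with Haldane crossovers, selfing,
    bulk advancement), marker quality control (random imputation from allele
    frequencies, monomorphic and minor-allele-frequency filters), construction of
    genomic, pedigree and Gaussian-kernel relationship matrices, a Gibbs-sampling
    engine for Bayesian genomic prediction (GBLUP, pedigree + GBLUP, reproducing
    kernel Hilbert space regression with kernel averaging, and their combination),
    within- and between-family cross-validation, line-mean heritability and
    realized genetic gain arithmetic, Nei's standard genetic distance for
    diversity tracking, and an in-silico recurrent-selection scheme engine that
    chains these stages over multiple selection cycles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
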