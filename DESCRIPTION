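Package: pzfold
Title: Nearest-Neighbor Thermodynamics, Folding, and Sequence Design for DNA
    with the Expanded P-Z Alphabet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Secondary-structure thermodynamics for DNA extended with the
    synthetic AEGIS bases P (a purine analog) and Z (a pyrimidine analog),
    allowing C-G, A-T, P-Z and wobble G-Z base pairs. Provides nearest-neighbor
    stack and loop parameter tables with rule-based extrapolation to the
    expanded alphabet, two-state duplex stability and melting-temperature
    prediction, staged ordinary-least-squares fitting of stack parameters from
    optical melting summaries, global six-parameter fitting of two-concentration
    absorbance melting curves, a partition-function folding engine (pair
    probabilities, minimum free energy structures, normalized ensemble defect),
    and stochastic inverse design that minimizes the normalized ensemble defect
    with biased base-pair selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
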