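Package: hegwas
Title: Semi-Parallel GWAS over Simulated Homomorphic Encryption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Runs the semi-parallel genome-wide association algorithm on a
    simulated CKKS homomorphic-encryption backend. Ciphertexts are modelled
    as vectors of complex slots with exact arithmetic, noise-budget (level)
    bookkeeping and an operation meter that reports the multiplicative depth
    of the full circuit. Provides the four packed-matrix encodings
    (column-packed, column-compact-packed, row-packed and
    row-expanded-packed) and their multiplication algorithms, approximate
    logistic regression with a fixed Hessian bound and a degree-7 polynomial
    sigmoid, slot-wise Newton reciprocals, complex packing of two SNPs per
    slot, batched per-SNP association statistics, cleartext reference
    oracles, a synthetic cohort generator and accuracy evaluation helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
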