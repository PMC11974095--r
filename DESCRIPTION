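Package: evocn
Title: Evolution-Aware Haplotype-Specific Copy Number Calling for Single-Cell DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers haplotype-specific integer copy-number profiles for single
    cells from low-pass single-cell DNA sequencing read depths and B-allele
    frequencies. Profiles are constrained to arise from sequences of copy
    number aberrations (amplifications, deletions, whole-genome duplication)
    applied to the normal diploid genome; a convolutional policy network
    defines a generative distribution over these mutation trajectories and is
    trained by importance-sampled policy-gradient reinforcement learning to
    maximise the probability of the observed data across all cells, guided by
    a fast per-cell maximum-likelihood initialiser. Includes a fitness-driven
    tumour evolution simulator, evaluation metrics on fixed-size genomic bins,
    and an orthogonal validation test based on truncal somatic SNVs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
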