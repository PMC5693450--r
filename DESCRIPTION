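Package: tomassay
Title: Computational Assay of Theory-of-Mind Sophistication in Dyadic Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates repeated dyadic hide-and-seek games between learning
    agents of calibrated Theory-of-Mind (ToM) sophistication, fits ten
    candidate learning models (biased Nash, win-stay/lose-switch,
    reinforcement learning, 0-ToM, influence learning and recursive 1-/2-ToM
    in cooperative and competitive variants) to trial-by-trial choice
    sequences by variational-Laplace inference, derives within-subject
    ToM-family posteriors and group-level random-effects model frequencies,
    decomposes choices into exponential Volterra history kernels, and relates
    ToM sophistication to species-level features such as endocranial volume
    and social group size. Includes a synthetic-cohort generator with known
    ground truth for confusion and parameter-recovery analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
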