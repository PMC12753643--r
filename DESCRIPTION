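Package: arbRL
Title: Dual-System Reinforcement Learning with Dynamic Arbitration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, maximum-likelihood fitting and analysis of dual-system
    reinforcement-learning models of probabilistic reversal learning. Implements
    stimulus-based and action-based value learners, their static and dynamic
    combinations in which a trial-varying arbitration weight tracks the relative
    reliability of the two systems, and a generalisation with a subject-level
    baseline signal-strength ratio. Includes a generative task simulator
    (What-only and What/Where reversal blocks), entropy-based strategy metrics
    (ERDS), effective arbitration weights and rates, multi-start maximum-likelihood
    estimation with block-wise cross-validation, permutation tests, and model- and
    parameter-recovery pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Rcpp, stats, utils, graphics, grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
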