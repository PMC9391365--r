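Package: nfdrt
Title: Simulation and Analysis of Real-Time fMRI Neurofeedback Regulation Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying self-regulation of the dopaminergic midbrain
    (SN/VTA) with real-time fMRI neurofeedback. Implements the online feedback
    computation (REST-tail reference, three-volume moving average, percent
    signal change with polarity and display clamping), the degree-of-regulation
    transfer (DRT) statistic, temporal-difference learning signals and their
    GLM-based tracking with parametric modulators, psychophysiological
    interaction (PPI) connectivity designs, monetary incentive delay (MID)
    reward-sensitivity contrasts, and the associated group-level statistics
    (rank and product-moment correlations with bootstrap, comparison of
    independent correlations, one-way ANOVA, Kruskal-Wallis, pooled t,
    conjunction/disjunction, BH-FDR). A seed-deterministic synthetic-data
    generator produces block-design neurofeedback sessions driven by a softmax
    reinforcement-learning agent, coupled region time series with AR(1) noise,
    drift and physiological components, and MID sessions, so the whole pipeline
    is testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
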