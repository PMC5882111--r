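Package: rmsprt
Title: Recursive Multi-Hypothesis Sequential Probability Ratio Test Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of decision-making with the recursive
    multi-hypothesis sequential probability ratio test (rMSPRT): a delayed
    feedback Bayesian sequential decision algorithm driven by lognormal
    inter-spike-interval evidence with statistics drawn from macaque MT
    recordings during the random dot motion task. Provides the packaged
    MT statistics registry, lognormal evidence generators and spike-train
    utilities, the recursive inference core with threshold calibration,
    a mapping of the algorithm's internal variables onto the
    cortico-basal-ganglia-thalamo-cortical loop, conversion of decision
    sample sizes to reaction times, and the information-loss /
    information-depletion estimation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
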