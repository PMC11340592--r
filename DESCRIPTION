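Package: habfilter
Title: Habituation as Bayes-Optimal Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates habituation and sensitization as Bayes-optimal filtering
    of noisy sensory signals. A Gaussian-process prior over a latent
    stimulus-intensity state is conditioned on the signal history, and the
    behavioral response is the posterior probability that the state exceeds a
    salience threshold. Includes declarative stimulus-protocol builders
    (repeated series, rest periods, common-test designs, novel-stimulus
    insertions), a generative mode for parameter-recovery checks, a phenomena
    battery that operationalizes the canonical characteristics of habituation
    (simple habituation, spontaneous recovery, potentiation, frequency and
    intensity sensitivity, below-zero effects, stimulus specificity,
    dishabituation and its habituation), and a command-line front end for
    config-driven simulation runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
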