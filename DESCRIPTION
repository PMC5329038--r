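Package: tomsim
Title: Cognitive Models of Strategy Selection in Second-Order False-Belief Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded simulators of two ACT-R-style cognitive models of how
    five-year-olds select and revise theory-of-mind strategies in a repeated
    second-order false-belief task: an instance-based learning model in which
    strategy chunks compete by base-level activation in declarative memory,
    and a reinforcement-learning model in which strategy production rules
    compete by noisy utilities under time-discounted reward. Includes the task
    environment (story facts, k-th-order answer derivation, feedback and
    answer classification), cohort simulation of virtual children with
    per-repetition strategy-proportion and subsymbolic traces, crossover
    detection, and chi-square comparison of model-predicted wrong-answer
    distributions against an empirical fixture.
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
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
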