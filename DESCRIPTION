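Package: policycompress
Title: Policy Compression Analysis of Two-Alternative Perceptual Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing capacity-limited decision making in
    two-alternative forced-choice (2AFC) tasks. Estimates policy complexity
    (the mutual information between stimulus states and actions) and
    per-trial policy cost from choice data, computes the optimal
    reward-complexity frontier with the Blahut-Arimoto algorithm, fits the
    capacity-limited softmax policy P(a|s) proportional to
    exp[beta*Q(s,a) + log P(a)] by maximum likelihood, simulates a
    cost-penalised actor-critic whose reward prediction error carries a
    policy-complexity penalty, and regresses outcome-locked dopamine-like
    responses on outcome, action value and policy cost. A synthetic-data
    generator reproduces the statistical structure of the task (9 signed
    contrast states, blockwise 2:1 reward asymmetry, session-varying
    inverse temperature and choice bias) so the full pipeline runs without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
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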