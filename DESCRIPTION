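Package: sleepnet
Title: Three-Population Firing-Rate Network Model of the Sleep-Wake Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a sleep-wake regulatory network of three neural
    populations (Wake-, NREM- and REM-promoting) coupled by excitatory and
    inhibitory synapses and driven by a homeostatic sleep drive. Population
    activity follows a firing-rate formalism integrated with a fixed-step
    fourth-order Runge-Kutta scheme with weak additive Gaussian noise.
    Trajectories are scored into hypnograms (Wake/NREM/REM), from which
    sleep-architecture metrics (state durations, percentages, episode and
    transition counts, NREM and REM latencies) are computed. Tools are
    included for systematic synaptic-weight scaling and lesion experiments
    across all six pathways, joint two-pathway sweeps, replicate stochastic
    simulations, and one-way ANOVA with Tukey post-hoc comparisons against
    the control condition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
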