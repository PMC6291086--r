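Package: sleepcost
Title: Opportunity-Cost Extension of the Two-Process Sleep Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and calibration toolkit for a utility-based
    generalization of the two-process model of sleep regulation. A homeostatic
    sleep-pressure process and a circadian cycle are combined with a
    time-varying opportunity cost of sleep: each period the animal makes a
    myopic binary sleep/wake choice trading foraging utility against the
    penalty for straying from its circadian cycle, with a fixed cost of
    switching state. Includes the classic deterministic threshold-switching
    model as a baseline, species parameter presets (elephants and three-toed
    sloths, captive and wild), noise-free "stylized day" limit-cycle analysis
    of polyphasic sleep, episode and daily sleep-hour summaries, and
    simulated-method-of-moments calibration with common random numbers and
    Nelder-Mead search, plus a sensitivity-scenario runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
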