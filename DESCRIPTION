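Package: meththerm
Title: Mechanistic Modeling of Methamphetamine-Evoked Temperature Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic analysis of body-temperature responses to
    methamphetamine, injection stress, and orexin-receptor antagonism in
    rats. Couples a bi-exponential absorption-elimination pharmacokinetic
    model to a sigmoidal firing-rate circuit (excitatory, inhibitory and
    high-dose-activated populations competing on a medullary relay and a
    sympathetic premotor output) and a first-order body-temperature ODE.
    Fits the drug-sensitive weights to group temperature time series by
    random-walk Metropolis-Hastings MCMC, summarizes posterior ensembles,
    tests between-dose differences with two-sample z-tests, and provides a
    seeded synthetic-data generator emulating the telemetry study design,
    activation-curve diagnostics and inhibition-failure simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
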