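Package: mmonset
Title: Independent Multimutation Model of Disease Age of Onset and Twin Concordance
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the independent multimutation model (MMM) of disease
    age of onset, in which susceptible individuals accumulate a fixed number of
    independent, exponentially timed internal changes and disease onset
    coincides with the last of them. Provides closed-form susceptible and
    population prevalence and incidence curves with a dimensionless biological
    clock-rate rescaling, least-squares fitting of the 3- and 4-parameter model
    to age-binned cumulative incidence data with an integer search over the
    mutation count, the monozygote/dizygote twin subcohort concordance algebra
    with its inversion formulas (prevalence from concordance, inherited
    susceptibility from concordance pairs), cohort-average concordance,
    equivalent-age and clock-rate solvers, exact simulators for onset ages and
    twin cohorts, and a reference fixture of classical pre-1970 schizophrenia
    twin studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
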