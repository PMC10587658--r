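Package: strokepgx
Title: Cost-Effectiveness of CYP2C19-Guided Antiplatelet Therapy After
    Ischaemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model for point-of-care
    CYP2C19 loss-of-function testing to guide antiplatelet prescription
    (clopidogrel, modified-release dipyridamole plus aspirin, or aspirin)
    in secondary prevention of ischaemic stroke.  A decision tree assigns
    treatment by genotype and drug tolerance; a five-state annual-cycle
    Markov cohort model accumulates discounted healthcare costs and
    quality-adjusted life-years over a lifetime horizon.  Provides
    incremental analysis (ICER, net health and monetary benefit with
    population scaling), probabilistic sensitivity analysis with
    method-of-moments parameter distributions and cost-effectiveness
    acceptability curves, deterministic one-way threshold search, and
    generators for internally consistent synthetic parameter sets and
    life tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
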