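Package: hicr
Title: Heat-Induced Calcium Release Analysis for Microscopic Heating Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of single-cell calcium imaging experiments in
    which brief, optically applied heat pulses are delivered by a focused
    infrared laser. Converts temperature-dye (Eu-TTA) quenching traces to local
    temperature rises via published calibration slopes, corrects photobleaching,
    computes per-cell calcium burst statistics (dF_max/F0 for cytosolic
    indicators, dF_min/F0 for ER-luminal indicators), derives a responder
    threshold from spontaneous fluctuations by least-squares fitting of a
    Gaussian cumulative distribution function, and estimates the
    heat-sensitivity threshold dT_th (the temperature rise at 50% response
    probability) by logistic maximum likelihood with bootstrap confidence
    intervals. Includes a ground-truthed synthetic-data generator that emulates
    the microheating experiment end to end, down to rendered image stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
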