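Package: sancpace
Title: Seizure-Induced Sinus Arrhythmias in a Mouse Sinoatrial Node Cell Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates seizure-induced sinus arrhythmias in a single mouse
    sinoatrial nodal cell (SANC). A reduced Hodgkin-Huxley pacemaker model
    (L- and T-type Ca currents, funny current, delayed-rectifier and
    muscarinic K currents, Na/K pump, Na-Ca exchanger) is driven by an
    autonomic clamping protocol in which sympathetic and parasympathetic
    levels are stepped to fixed ictal values and then linearly ramped to
    postictal values. Circadian (zeitgeber-time dependent) and vigilance
    (sleep/wake) state modulation of parasympathetic tone, body temperature
    and local circadian HCN expression is included. Tools are provided for
    action-potential detection, firing-rate and burst metrics, classification
    of firing windows as rhythmic, irregular or no-firing, two-dimensional
    parameter-space maps with a nine-region ictal-by-postictal taxonomy, and
    a synthetic membrane-potential trace generator with known ground truth
    for validating the analysis stages.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
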