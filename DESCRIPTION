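Package: leadheat
Title: RF-Induced Lead-Tip Heating and Resonant Length of Implanted
    Insulated Wires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models radio-frequency induced heating at the tip of an
    insulated implanted lead during MRI. Computes complex wavenumbers of
    lossy media and of an insulated conductor embedded in conductive
    tissue (insulated antenna theory), evaluates simple-exponential and
    transmission-line transfer functions for the lead-tip voltage and
    relative temperature rise versus lead length, solves the
    transcendental equations for the resonant length, integrates the
    tangential electric field along arbitrary wire paths through sampled
    vector fields, and fits model curves to temperature-rise
    measurements with transmit-gain correction, RMSE and AIC model
    comparison. Includes a command-line interface and synthetic field
    and measurement generators so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
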