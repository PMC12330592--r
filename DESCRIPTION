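Package: durakit
Title: Characterization and Analysis Toolkit for Transparent Micro-ECoG
    Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Engineering and electrophysiology analytics for surface
    micro-electrocorticography (uECoG) arrays built on transparent
    artificial-dura substrates. Provides equivalent-circuit simulation of
    electrode impedance spectra and stimulation voltage transients;
    impedance-spectrum analytics (thermal noise, theoretical SNR,
    electroplating charge cutoffs, channel yield); the charge-balanced
    stimulation pipeline (access-voltage isolation, water-window
    compliance, charge-injection capacity); Fresnel multilayer
    transmission, spectrometer processing and geometric optical-access
    accounting for array layouts; bilayer plate mechanics (effective
    modulus, flexural rigidity, membrane deflection); and a synthetic
    multichannel recording generator with the matching trial-based
    band-power, spectrogram and spike analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    mclust,
    optparse
Config/testthat/edition: 3
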