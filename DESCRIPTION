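Package: imkmn
Title: Integrated Microdosimetric-Kinetic Modelling of Cell Survival and
    Micronuclei Formation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Biophysical dose-response modelling with the integrated
    microdosimetric-kinetic (IMK) model extended to micronuclei (MN)
    formation. Provides saturation-corrected microdosimetric quantities
    (y*, z1D*) from tabulated lineal-energy spectra, Lea-Catcheside
    protraction factors for continuous and fractionated irradiation
    schedules, closed-form survival and MN dose-response predictions,
    relative biological effectiveness (RBE) for both endpoints, Metropolis
    MCMC parameter estimation with credible-band propagation, a synthetic
    data generator for spectra and noisy dose-response datasets, and file
    readers and writers plus a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
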