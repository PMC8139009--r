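Package: tpbecm
Title: Tissue-Property-Based Equivalent Circuit Models of Layered Body
    Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Parameterizes conductivity, permittivity and layer thickness of
    a layered body structure (for example skin, fat and muscle under surface
    electrodes) into an equivalent circuit of complex capacitors. Implements
    complex-permittivity algebra, the partial-capacitance composition of
    layered dielectrics with regression-corrected geometric factors
    (interdimensional factors), least-squares refitting of those factors from
    simulated capacitance data, layered-body impedance spectra with thickness
    and permittivity sweeps, and time-domain responses to transcutaneous
    electrical nerve stimulation pulses via harmonic decomposition and
    inverse FFT.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
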