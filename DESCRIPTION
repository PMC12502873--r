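Package: memsas
Title: Small-Angle and Spin-Echo Scattering Models for Membranes with
    Protein Inclusions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the elastic (SAXS/SANS) and inelastic (neutron spin-echo)
    small-angle scattering of lipid membranes carrying protein-like cylindrical
    inclusions. A membrane model (static slab stack or Gaussian fluctuating
    membrane) is combined with an independent in-plane model of the protein
    phase (hard-disc or Boolean overlapping discs) through a general
    correlation-function construction, yielding per-unit-area intensities and
    normalized intermediate scattering functions. Includes stochastic
    realization samplers with an FFT scattering oracle, weighted least-squares
    fitting of elastic curves and NSE surfaces, synthetic fixture generation,
    ASCII data readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
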