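Package: fcsrd
Title: Reaction-Diffusion Autocorrelation Models for Fluorescence
    Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form and exact (quadrature-based) autocorrelation
    functions G(t) for fluorescence correlation spectroscopy of a dye
    reversibly binding to a macromolecule (A + B <-> C) with coupled
    reaction-diffusion dynamics.  The exact route averages the
    single-species diffusion autocorrelation over the two-state
    occupation-time densities of the dye (Skellam / modified-Bessel
    forms); the closed-form route uses a second-order moment expansion
    around the mean occupation fraction.  Includes the limiting regimes
    (effective diffusion, two-component diffusion, slow reaction, fast
    diffusion over immobile sites), applicability diagnostics for the
    moment expansion, correlogram I/O, weighted nonlinear least-squares
    fitting, and brute-force Monte Carlo oracles for auditing any
    parameter point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
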