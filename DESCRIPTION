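Package: shsbind
Title: Second-Harmonic Scattering Titration Analysis of Protein
    Adsorption on Charged Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free analysis of angle-resolved second-harmonic
    scattering (SHS) titrations of proteins onto charged colloidal
    nanoparticles. Provides charge-potential relations for spheres and
    planes in symmetric electrolytes (Debye screening, the Ohshima
    sphere approximation and the planar Grahame equation, with numerical
    inversion), a depletion-corrected Langmuir adsorption isotherm with
    a closed-form solution, a nonlinear Rayleigh-Gans-Debye forward
    model for the SHS intensity including the field-aligned bulk
    third-order contribution of the diffuse double layer, and a global
    nonlinear least-squares pipeline that recovers apparent binding
    constants, monolayer capacities and apparent Gibbs free energies
    with bootstrap uncertainties. A synthetic-data module generates
    titration curves and scattering patterns with the statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
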