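Package: stoichspindle
Title: Stoichiometric Model of Cortical Pulling Forces and Spindle Positioning
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulator of mitotic spindle positioning, elongation,
    and scaling in single-cell nematode embryos under the stoichiometric model
    of cortical pulling forces. Astral microtubules nucleate from centrosomes
    and bind cortically anchored force generators one microtubule at a time;
    quasi-steady attachment probabilities yield pulling forces that move the
    centrosomes under overdamped force balance inside a superellipsoid cell.
    Includes canonical experiment scenarios (asymmetric and symmetric layouts,
    single-aster centering, in-silico centrosome removal, cell-size and
    force-generator-number sweeps), sigmoid trait extraction (initial/final
    spindle length, elongation rate, centrosome distance), regression and
    partial-correlation machinery for discriminating spindle size-control
    models, and synthetic trait-table generators for the Timer, Limiting
    Component, and Boundary hypotheses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
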