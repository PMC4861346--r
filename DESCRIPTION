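Package: ionflux
Title: Whole-Cell Pump-Leak Flux Balance of Monovalent Ions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the whole-cell pump-leak flux balance of the monovalent
    ions Na+, K+, Li+ and Cl- under the mandatory constraints of macroscopic
    electroneutrality and osmotic balance. The model combines the Na/K (and
    Li/K) ATPase pump, Goldman-type electroconductive channels, NC, KC, LC,
    NKCC and LKCC cotransporters and Li/Na (Na/Na) countertransport, each
    characterised by a single rate coefficient. Functions are provided to
    solve the transcendental membrane-potential equation, integrate the
    transient dynamics to the balanced state, decompose every pathway into
    unidirectional influx and efflux (including coupled self-exchange),
    simulate and fit isotope tracer equilibration kinetics, and solve the
    inverse problem of recovering rate coefficients from measured balanced
    states. Parameter files in the DATAP layout and result files in the RESP
    layout are read and written, and a command-line interface is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
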