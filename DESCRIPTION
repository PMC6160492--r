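Package: lintflux
Title: Ratchet Transport Model of Navel Lint Accretion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative model of belly button lint (navel fluff) production.
    Breathing sets up a periodic relative motion between clothing and skin;
    the directional friction of body-hair cuticle scales rectifies that
    oscillation into a net root-to-tip drift of loose textile fibers, which
    accumulate in the navel. The package computes the per-fiber force balance
    and cycle-averaged sliding velocity, solves the resulting one-dimensional
    advection equation with a constant source both in closed form and with a
    conservative finite-volume upwind scheme, simulates the per-breathing-cycle
    ratchet stochastically, and reproduces the headline order-of-magnitude
    estimates (fabric tension, drift speed, fill time, accreted lint mass).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
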