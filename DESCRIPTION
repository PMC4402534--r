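Package: chromfiber
Title: Statistical Mechanics of Chromatin Fiber Force Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling and fitting of magnetic-tweezers
    force-extension curves of nucleosome arrays. Implements an extensible
    worm-like-chain description of bare DNA, a Hookean folded-fiber element,
    and a four-conformation partition-function model of nucleosome unwrapping
    (fiber, single wrap, extended intermediate, unwrapped). Provides
    per-nucleosome Levenberg-Marquardt fitting of equilibrium unfolding with
    heterogeneous fiber composition, t-test step detection and state
    assignment for the non-equilibrium high-force rupture staircase,
    conformational occupancy curves, and a seeded generator of synthetic
    pulling traces for validation and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
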