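Package: nomadcolony
Title: Nomadic-Colonial Population Dynamics and an Ecological Parrondo
    Paradox
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a two-strategy population model in which nomadic
    organisms decay exponentially while colonial organisms follow logistic
    growth with an Allee effect, coupled to a carrying capacity that the
    colony destroys and that regenerates in its absence. Capacity-triggered
    behavioral switching between the two individually losing strategies can
    paradoxically produce persistence and long-term growth. Provides
    event-located piecewise ODE integration (compiled right-hand side, via
    'deSolve') for fixed-threshold and adaptive switching rules, the
    Lambert-W survival theory (critical nomadic level, switching-level
    bounds), trajectory regime classification, shipped figure scenarios,
    full-precision CSV/JSON output, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
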