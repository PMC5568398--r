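Package: ltpasim
Title: Agent-Based Simulation of Leisure-Time Physical Activity Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time agent-based simulator in which adults'
    leisure-time physical activity (LTPA) emerges from the dynamic
    interplay of behavioral intention, the perceived built environment,
    and social influence from proximal networks and communities.
    Implements a moderated intention-behavior likelihood with
    saturating (inverted-U) moderation, distance-decayed access to
    activity places, small-world/random/complete social networks, a
    synchronous seeded update schedule, a deterministic mean-field
    recursion used as an independent verification oracle, reproducible
    synthetic scenario generation, and trajectory summaries and
    moderation-curve plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
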