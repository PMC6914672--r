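Package: needsim
Title: Needs-Based Agent Simulation of Longitudinal Human Activity Patterns
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates longitudinal activity diaries (sleeping, eating,
    commuting, working) for a working adult using an agent-based model driven
    by needs-based artificial intelligence. Four motivations (Rest, Hunger,
    Income, Travel) carry a satiation level in [0,1] that decays linearly or
    follows a clock-scheduled step function; when satiation falls to a
    threshold, objects in the agent's current environment advertise
    activities scored by an urgency weight, and the agent performs the
    highest-scoring one. Day-to-day behavioral variability is induced by
    sampling activity start times, end times, and durations from truncated
    normal distributions. Output is a minute-resolution activity diary with
    CSV serialization, summary statistics, and an analytic event-schedule
    oracle for verifying the simulation engine on zero-variance
    configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
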