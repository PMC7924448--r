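Package: specflow
Title: Speculative Task-Based Execution for Sequential Task Flows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A sequential task flow (STF) runtime with speculative execution
    of uncertain tasks, i.e. tasks that may or may not write the data they
    declare in maybe-write mode. The runtime derives the dependency graph
    from per-datum access modes, automatically constructs copy, speculative
    and select tasks, and manages speculative task groups so that a parallel
    or simulated execution always produces the payloads of the sequential
    reference execution. Includes closed-form and Monte Carlo evaluation of
    the expected speedup of predictive and eager speculation, and a
    Metropolis Monte Carlo / replica exchange Monte Carlo particle simulator
    (Lennard-Jones energies) that exercises the speculation mechanism end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
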