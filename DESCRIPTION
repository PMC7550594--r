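Package: groupmind
Title: Optimal Communication Networks for Collective Decision Making
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of group decision making in which agents
    with partial access to an observable environment refine their beliefs by
    costly observation and cheaper one-directional communication, together
    with a genetic-algorithm optimizer that evolves the group's weighted
    directed communication network and individual traits (suggestibility,
    communication activity, observation activity) under three optimality
    definitions: consensus, well-informedness, or both. Includes network
    characterization tools (cycle-based hierarchy, weighted degree
    specialization), parameter-sweep experiment orchestration with trend
    reports, and tidy accessors for all fitted objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
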