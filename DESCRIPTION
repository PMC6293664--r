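Package: heritsim
Title: Multilevel Heritability of Collective Traits in Clonal Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates clonal populations of particles (cells) nested within
    reproducing collectives (nascent multicellular groups) and quantifies how
    broad-sense heritability at the collective level relates to heritability
    at the particle level. Provides an agent-based growth model with two
    non-genetic noise sources (developmental instability of particle size and
    a per-collective environmental modifier) plus optional variation in the
    number of particles per collective; trait maps from member-cell phenotypes
    to collective traits (volume, diameter, upward swimming speed, survival
    under size-selective predation); heritability estimators based on
    parent-offspring regression and balanced nested-ANOVA sums of squares;
    and parameter-sweep drivers with CSV/JSON export and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
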