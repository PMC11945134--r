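Package: mabcr
Title: Marker-Assisted Backcross Breeding with InDel Marker Panels
Version: 0.1.0
Authors@R:
    person("mabcr", "developers", email = "mabcr@example.org", role = c("aut", "cre"))
Description: Tools for marker-assisted backcross (MABC) introgression
    programs: design of InDel marker panels from two-parent variant data
    (genotype-quality, length-difference, flank GC, tandem-repeat and
    reference-divergence screening, followed by even centiMorgan spacing),
    recurrent-parent background-recovery scoring Rg = (I+S)/(2I) x 100,
    chi-square segregation tests, 2^-ddCt relative-expression calculations,
    and a forward-in-time meiosis simulator (Poisson crossovers, Haldane
    model) that reproduces expected background-recovery trajectories
    across backcross generations. Includes a synthetic-data module that
    generates maize-like genetic maps, founder genomes, candidate InDel
    site tables and backcross populations, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
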