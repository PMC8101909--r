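Package: haplopop
Title: Mitochondrial Haplotype Population Structure and Demographic History
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of aligned mitochondrial DNA sequences sampled from
    hierarchically structured populations (range > area > site): haplotype
    collapsing and site classification, NUMT screening by translation,
    Kimura two-parameter distances, Nei haplotype and nucleotide diversity,
    hierarchical analysis of molecular variance (AMOVA) with Phi-statistics
    and permutation tests, Raymond-Rousset exact tests of population
    differentiation, statistical-parsimony (TCS-style) haplotype networks
    with loop resolution, Tajima's D and Fu's Fs neutrality tests,
    mismatch-distribution fitting under the sudden-expansion model with
    parametric bootstrap, and expansion-time dating. Includes a coalescent
    simulator (constant size, step expansion, two-range split) and a
    deterministic synthetic dataset emulating a two-range outbreak sampling
    design, so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
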