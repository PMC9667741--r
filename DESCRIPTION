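Package: planthgt
Title: Detection and Assessment of Microbe-to-Plant Horizontal Gene Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-mining toolkit for identifying microbe-originated
    horizontally transferred genes in plant genomes from taxonomy-annotated
    homology hit tables, and for assessing the calls downstream: a
    best-hit/majority screening rule with donor inference, a support-aware
    gene-tree nesting test of phylogenetic incongruence, codon adaptation
    index (RSCU/CAI) scoring of expressivity against a highly expressed
    reference set, rigid-body superposition (Kabsch) with TM-score fold
    comparison of CA traces, and stress-category assignment from a keyword
    lexicon. Ships a fully deterministic planted-HGT world simulator
    (lineage-structured homolog families with codon bias, divergence-scaled
    hit scores, grafted gene trees, tunable amelioration) so the whole
    pipeline is benchmarkable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    phytools,
    seqinr,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
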