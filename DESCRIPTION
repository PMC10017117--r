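Package: cladeclock
Title: Clade-Wise Root-to-Tip Regression for Temporal Signal in Dated
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans every internal node of a rooted phylogenetic tree with
    heterochronously sampled tips for temporal signal, by regressing
    node-to-tip genetic distance on tip sampling date.  Under a strict
    molecular clock the slope of this regression estimates the substitution
    rate and the x-intercept estimates the age of the node, so a
    statistically significant positive slope within a clade indicates that
    the clade is measurably evolving over its sampling window and is a
    candidate for tip-dating inference.  Includes readers for Newick and
    Nexus trees with sampling dates embedded in tip labels, eligibility
    rules for when the per-node regression is meaningful, a FigTree-style
    annotated Nexus writer, variant-sites-only FASTA extraction for clades
    with signal, a seeded strict-clock tree simulator for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
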