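Package: orthocodon
Title: Comparative Codon Usage and Substitution Asymmetry in Orthologous
    Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylum-scale comparative analysis of codon usage from
    per-species coding sequences and orthologue groups. Derives core
    one-per-species orthologue sets from reciprocal best hits, back-translates
    protein alignments into gap-free codon alignments and concatenated
    super-sequences, and computes compositional statistics: GC content by
    codon position, relative synonymous codon usage (RSCU), Wright's
    effective number of codons (ENC), neutrality regressions and
    ENC-vs-GC3 expectations. Species are clustered on RSCU with a
    majority-rule consensus over clustering settings, genes are ordinated by
    codon frequencies, and preferred codons are called from
    expression-stratified gene sets. Asymmetric 20x20 amino-acid and 61x61
    codon substitution matrices between species pairs support chi-square
    usage-deviation and reciprocal-asymmetry tests, substitution
    classification, and quantification of the two-hit (double-substitution)
    signal. A coupled-sampling sequence simulator generates ortholog
    families with species-specific GC3 targets, expression-linked codon
    preference and tunable two-hit coupling, so the full pipeline can be
    exercised and validated without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
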