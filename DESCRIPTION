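Package: PSGscreen
Title: Genome-Wide Screening and Characterization of Positively Selected Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for screening positively selected genes (PSGs) between
    two related plant genomes from pairwise Ka/Ks estimates, and for
    characterizing the resulting gene set. Implements the Nei-Gojobori (1986)
    and Yang-Nielsen (2000) counting estimators of synonymous and
    nonsynonymous divergence, Ks-based saturation filtering and Ka/Ks
    thresholding, chi-square / Monte-Carlo Fisher / permutation tests of
    chromosomal distribution, hypergeometric term enrichment with
    Benjamini-Hochberg correction, tissue-specificity classification of
    expression profiles with whole-genome-triplication retention
    stratification, and genic-region (promoter/UTR5/exon/intron/UTR3)
    weighted DNA-methylation profiling at CG/CHG/CHH contexts with
    transposable-element stratification. A codon-level GY94-style simulator
    and genome/expression/methylome generators provide fully synthetic study
    sets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, Epigenetics, GeneExpression, Software
RoxygenNote: 7.3.3
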