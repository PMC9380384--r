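Package: somaguide
Title: Allele-Specific CRISPR-Cas9 Guide Design Against Tumor-Unique Somatic Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Nominates SpCas9 guide RNAs that target tumor-specific somatic
    mutations (SNVs and small indels) while having no recognizable target in
    the matched normal genome. Provides PAM scanning on reconstructed tumor
    haplotypes, allele-specificity classification (PAM gain, seed mismatch,
    indel disruption), mismatch-tolerant off-target search against the normal
    genome via a k-mer pigeonhole index, heuristic multi-guide panel selection,
    Monte-Carlo estimation of the number of suitable target sites per tumor,
    and clonal-persistence analysis of guide panels under ongoing tumor
    evolution, together with a synthetic-data generator for background genomes,
    somatic variant spike-ins and passaged single-cell clones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
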