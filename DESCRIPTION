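Package: gvptools
Title: Genetically Variant Peptide Detection and Forensic Profile Statistics
Version: 0.1.0
Authors@R: person("Forensic", "Proteomics Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for protein-based human identification from shotgun
    proteomics data. Builds variant-aware protein reference databases from
    non-synonymous SNP (nsSNP) annotations, performs in-silico tryptic
    digestion and enumeration of genetically variant peptides (GVPs),
    filters peptide-spectrum matches with the standard forensic exclusion
    criteria (engine score, precursor mass error, allele frequency,
    post-translational modification, chemically confusable substitutions,
    gene uniqueness, and alternative-allele fragment evidence), collates
    per-subject imputed nsSNP allele profiles, validates them against truth
    genotypes, and computes population random-match probabilities with a
    Jeffreys-prior estimator, product rule, parametric-bootstrap confidence
    intervals, and cross-population likelihood ratios. Includes a
    synthetic-data generator (Hardy-Weinberg genotype panels plus a binary
    peptide-detection model) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    VariantAnnotation,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
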