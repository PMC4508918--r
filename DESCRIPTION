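Package: admixscan
Title: Three-Way Admixture Analysis of Local-Ancestry Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for three-way admixed cohorts built on
    per-haplotype local-ancestry segment calls and SNP genotypes. Computes
    pairwise allele-sharing distances and their principal components,
    per-individual global ancestry proportions (tract-length aggregation and
    supervised EM against reference allele frequencies), the X-versus-autosome
    admixture difference ratio with bootstrap confidence intervals, and a
    genome-wide trinomial ancestry-enrichment scan with exact multinomial
    tail probabilities and Benjamini-Hochberg FDR control. Includes a forward
    simulator of admixed diploid cohorts with sex-biased founding
    contributions, Poisson recombination on autosomes and X, and
    Balding-Nichols ancestral allele frequencies, so the full pipeline runs
    on synthetic data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
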