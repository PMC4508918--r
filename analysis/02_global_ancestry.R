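#!/usr/bin/env Rscript
# Stage 2: global ancestry.
#
# From the simulated cohort's files (as a real run would start from
# local-ancestry calls and a VCF): per-individual ancestry fractions by
# tract-length aggregation, supervised-EM ancestry proportions against
# the ancestral allele frequencies, and a PCA of pairwise allele-sharing
# distances including simulated unadmixed reference individuals.

library(admixscan)

dir.create("results/global", showWarnings = FALSE, recursive = TRUE)
segments <- read_segments("results/cohort/segments.tsv")
gm <- read_genotypes_vcf("results/cohort/genotypes.vcf")
freqs <- read_allele_freqs("results/cohort/allele_freqs.tsv")

records <- fractions_from_tracts(segments)
write.table(records, "results/global/tract_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

em <- suppressWarnings(supervised_admixture_em(gm, freqs))
em_df <- data.frame(individual = rownames(em$Q), em$Q, row.names = NULL)
write.table(em_df, "results/global/em_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tot <- records[records$compartment == "total", ]
tot <- tot[match(em_df$individual, tot$individual), ]
agree <- max(abs(as.matrix(em_df[, ANCESTRIES]) -
                   as.matrix(tot[, ANCESTRIES])))
cat(sprintf("EM vs tract fractions: max per-individual deviation %.3f,\n",
            agree))
cat(sprintf("  cohort-mean deviation %.4f over %d SNPs\n",
            max(abs(colMeans(as.matrix(em_df[, ANCESTRIES])) -
                      colMeans(as.matrix(tot[, ANCESTRIES])))), em$n_snps))

# unadmixed reference genomes drawn from the same allele frequencies
lens <- tapply(segments$end, segments$chrom, max)
ref_ids <- sprintf("ref_%s%02d", rep(tolower(ANCESTRIES), each = 10), 1:10)
ref_anc <- rep(ANCESTRIES, each = 10)
ref_seg <- do.call(rbind, lapply(seq_along(ref_ids), function(i)
  do.call(rbind, lapply(names(lens), function(cc)
    data.frame(individual = ref_ids[i], haplotype = 0:1, chrom = cc,
               start = 0, end = lens[[cc]], ancestry = ref_anc[i])))))
ref_gm <- sample_genotypes(list(segments = ref_seg, ids = ref_ids,
                                sexes = setNames(rep("F", 30), ref_ids)),
                           freqs, seed = 271)
gm$samples <- c(gm$samples, ref_gm$samples)
gm$dosage <- cbind(gm$dosage, ref_gm$dosage)
gm$ploidy <- cbind(gm$ploidy, ref_gm$ploidy)

asd <- allele_sharing_distance(gm)
write.table(asd$dist, "results/global/asd_matrix.tsv", sep = "\t",
            quote = FALSE)
pca <- pca_project(asd, 4)
write.table(data.frame(individual = rownames(pca$scores), pca$scores),
            "results/global/pca_coords.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PCA of allele-sharing distances (cohort + 30 references):\n"))
cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of the variation\n",
            100 * pca$explained[1], 100 * pca$explained[2]))
cat("Outputs in results/global\n")
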