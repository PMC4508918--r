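#!/usr/bin/env Rscript
# Stage 4: genome-wide ancestry-enrichment scan.
#
# Per-locus three-way chromosome counts at 1 Mb loci, the trinomial
# probability of each observed combination given the cohort-average
# proportions (the headline score), the calibrated exact multinomial
# tail, BH q-values, log-fold enrichments, the combination-frequency
# heatmap matrix, and significant segments merged and annotated with a
# synthetic gene set.

library(admixscan)

dir.create("results/scan", showWarnings = FALSE, recursive = TRUE)
segments <- read_segments("results/cohort/segments.tsv")
windows <- read_locus_windows("results/cohort/windows.bed")

scan <- scan_genome(segments, windows, alpha_p = 1e-9, score = "pmf")
write.table(as.data.frame(scan), "results/scan/enrichment_scan.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
p <- attr(scan, "expected")
cat(sprintf("Cohort-average proportions: AFR %.3f, NAM %.3f, EUR %.3f\n",
            p[1], p[2], p[3]))
cat(sprintf("%d loci scanned; %d significant at pmf < 1e-9\n",
            sum(!is.na(scan$score)), sum(scan$significant)))
scan_t <- scan_genome(segments, windows, alpha_p = 1e-9,
                      score = "exact_tail")
cat(sprintf("%d significant at exact-tail P < 1e-9 (min q = %.3g)\n",
            sum(scan_t$significant), min(scan_t$q_value, na.rm = TRUE)))

grid <- combination_frequency_grid(scan)
write.table(grid, "results/scan/combination_grid.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
mh <- make_manhattan_table(scan)
write.table(mh, "results/scan/manhattan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# synthetic gene annotation spread over the autosomes
set.seed(77)
lens <- cohort_sim_config()$chrom_lengths
genes <- do.call(rbind, lapply(names(lens)[names(lens) != "chrX"],
  function(cc) {
    s <- sort(sample.int(lens[[cc]] - 2e5, 40))
    data.frame(chrom = cc, start = s, end = s + sample(2e4:2e5, 40),
               name = sprintf("SYN_%s_%02d", sub("chr", "", cc), 1:40))
}))
merged <- annotate_genes(merge_significant_segments(scan), genes)
write.table(merged, "results/scan/enriched_segments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d merged enriched segments (%d carrying genes)\n",
            nrow(merged), sum(nzchar(merged$genes))))
cat("Outputs in results/scan\n")
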