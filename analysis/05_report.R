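#!/usr/bin/env Rscript
# Stage 5: run summary and chromosome paintings.

library(admixscan)

dir.create("results/report", showWarnings = FALSE, recursive = TRUE)
segments <- read_segments("results/cohort/segments.tsv")
records <- fractions_from_tracts(segments)
asym <- read.table("results/sexbias/delta_admix.tsv", header = TRUE,
                   sep = "\t")
scan <- scan_genome(segments,
                    read_locus_windows("results/cohort/windows.bed"))

summ <- make_summary(records, asym, scan)
writeLines(summ, "results/report/summary.txt")
cat(summ, sep = "\n")

# paintings of the two most contrasted individuals (max / min EUR)
tot <- records[records$compartment == "total", ]
picks <- tot$individual[c(which.max(tot$EUR), which.min(tot$EUR))]
for (id in picks)
  write_painting_bed(segments[segments$individual == id, ],
                     file.path("results/report",
                               paste0("painting_", id, ".bed")))
cat("\nPaintings written for", paste(picks, collapse = ", "),
    "in results/report\n")
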