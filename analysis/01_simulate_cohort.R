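#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Forward-simulates a 60-individual, three-way admixed diploid cohort
# under the default study conditions: six generations of random mating,
# founder proportions averaging (AFR, NAM, EUR) = (0.073, 0.181, 0.746)
# with strongly European paternal and Native-American maternal founding,
# a 22-autosome + X genome, and ~10,000 SNPs drawn from Balding-Nichols
# diverged allele frequencies (F = 0.15). Writes the same file formats a
# real local-ancestry pipeline would consume.

library(admixscan)

out <- "results/cohort"
cfg <- cohort_sim_config(n_snps_per_chrom = 435, seed = 42)
print(cfg)

sim <- simulate_pedigree_cohort(cfg, out_dir = out)
write_locus_windows(make_locus_windows(cfg$chrom_lengths, 1e6),
                    file.path(out, "windows.bed"))

tot <- sim$truth[sim$truth$compartment == "total", ]
cat(sprintf("\nSimulated %d individuals (%d segments, %d SNPs)\n",
            length(sim$ids), nrow(sim$segments), nrow(sim$freqs)))
cat(sprintf("Cohort mean ancestry: AFR %.1f%%, NAM %.1f%%, EUR %.1f%%\n",
            100 * mean(tot$AFR), 100 * mean(tot$NAM), 100 * mean(tot$EUR)))
cat(sprintf("EUR range across individuals: %.1f%%-%.1f%%\n",
            100 * min(tot$EUR), 100 * max(tot$EUR)))
cat("Outputs in", out, "\n")
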