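#' Default chromosome lengths for simulated cohorts
#'
#' Human-like genome: 22 autosomes plus X, lengths rounded to the nearest
#' megabase from the hg19 assembly. Using the full chromosome count matters
#' for the sampling properties of genome-wide ancestry fractions (fractions
#' average over independently segregating chromosomes).
#'
#' @return Named numeric vector of lengths in base pairs, names
#'   `chr1`..`chr22`, `chrX`.
#' @export
default_chrom_lengths <- function() {
  c(chr1 = 249e6, chr2 = 243e6, chr3 = 198e6, chr4 = 191e6, chr5 = 181e6,
    chr6 = 171e6, chr7 = 159e6, chr8 = 146e6, chr9 = 141e6, chr10 = 136e6,
    chr11 = 135e6, chr12 = 134e6, chr13 = 115e6, chr14 = 107e6,
    chr15 = 102e6, chr16 = 90e6, chr17 = 81e6, chr18 = 78e6, chr19 = 59e6,
    chr20 = 63e6, chr21 = 48e6, chr22 = 51e6, chrX = 155e6)
}

#' Configuration of a simulated admixed cohort
#'
#' Bundles every parameter of the forward simulator. Defaults describe a
#' cohort shaped like the admixed Medellin genomes: 60 diploid individuals,
#' six generations of random mating, founder ancestry proportions whose
#' sex-average is (AFR, NAM, EUR) = (0.073, 0.181, 0.746) with maximal
#' sex bias subject to that average — European-dominated paternal founders
#' and Native-American-enriched maternal founders, African founding on both
#' sides.
#'
#' @param n_individuals Number of diploid individuals in the final
#'   generation (and in every generation; population size is constant).
#' @param sex_ratio Fraction of males per generation, in `[0, 1]`.
#' @param n_generations Number of generations of random mating after the
#'   founders (>= 1).
#' @param founder_props_male,founder_props_female Ancestry probability
#'   3-vectors (AFR, NAM, EUR) from which founder haplotype ancestries of
#'   each sex are drawn; each must sum to 1.
#' @param chrom_lengths Named vector of chromosome lengths in bp; the X
#'   chromosome must be named `"chrX"` if present.
#' @param recomb_rate Expected crossovers per 1e8 bp per meiosis (a
#'   morgan-equivalent scale; 1.2 approximates the human sex-averaged map).
#' @param fst_divergence Balding-Nichols divergence F in (0, 1) between the
#'   three ancestral populations.
#' @param n_snps_per_chrom Number of simulated SNPs per chromosome.
#' @param seed Master integer seed; all stochastic draws derive from it
#'   through named substreams, so a fixed seed gives byte-identical output.
#' @return An object of class `cohort_sim_config`.
#' @seealso [simulate_pedigree_cohort()]
#' @export
cohort_sim_config <- function(n_individuals = 60,
                              sex_ratio = 0.5,
                              n_generations = 6,
                              founder_props_male = c(AFR = 0.073, NAM = 0,
                                                     EUR = 0.927),
                              founder_props_female = c(AFR = 0.073,
                                                       NAM = 0.362,
                                                       EUR = 0.565),
                              chrom_lengths = default_chrom_lengths(),
                              recomb_rate = 1.2,
                              fst_divergence = 0.15,
                              n_snps_per_chrom = 200,
                              seed = 1L) {
  if (!is.numeric(n_individuals) || n_individuals < 2)
    stop_param("n_individuals must be >= 2")
  if (!is.numeric(n_generations) || n_generations < 1)
    stop_param("n_generations must be >= 1")
  if (!is.numeric(sex_ratio) || sex_ratio < 0 || sex_ratio > 1)
    stop_param("sex_ratio must be in [0, 1]")
  fm <- check_prob_vector(founder_props_male, "founder_props_male")
  ff <- check_prob_vector(founder_props_female, "founder_props_female")
  if (is.null(names(chrom_lengths)) || any(!is.finite(chrom_lengths)) ||
      any(chrom_lengths <= 0))
    stop_param("chrom_lengths must be a named vector of positive lengths")
  if (!is.finite(fst_divergence) || fst_divergence <= 0 ||
      fst_divergence >= 1)
    stop_param("fst_divergence must be in (0, 1)")
  if (!is.finite(recomb_rate) || recomb_rate < 0)
    stop_param("recomb_rate must be non-negative")
  n_male <- round(sex_ratio * n_individuals)
  n_male <- min(max(n_male, 1L), n_individuals - 1L)
  structure(list(
    n_individuals = as.integer(n_individuals),
    sex_ratio = sex_ratio,
    n_male = as.integer(n_male),
    n_generations = as.integer(n_generations),
    founder_props_male = fm,
    founder_props_female = ff,
    chrom_lengths = chrom_lengths,
    recomb_rate = recomb_rate,
    fst_divergence = fst_divergence,
    n_snps_per_chrom = as.integer(n_snps_per_chrom),
    seed = as.integer(seed)
  ), class = "cohort_sim_config")
}

#' @export
print.cohort_sim_config <- function(x, ...) {
  cat("Simulated admixed cohort configuration\n")
  cat(sprintf("  individuals: %d (%d male / %d female), generations: %d\n",
              x$n_individuals, x$n_male, x$n_individuals - x$n_male,
              x$n_generations))
  cat(sprintf("  founder props  male : %s\n",
              paste(sprintf("%s=%.3f", ANCESTRIES, x$founder_props_male),
                    collapse = " ")))
  cat(sprintf("  founder props female: %s\n",
              paste(sprintf("%s=%.3f", ANCESTRIES, x$founder_props_female),
                    collapse = " ")))
  cat(sprintf("  chromosomes: %d (%s), recomb %.3g x/1e8bp, Fst %.3g\n",
              length(x$chrom_lengths),
              paste(utils::head(names(x$chrom_lengths), 3), collapse = ","),
              x$recomb_rate, x$fst_divergence))
  cat(sprintf("  SNPs/chrom: %d, seed: %d\n", x$n_snps_per_chrom, x$seed))
  invisible(x)
}
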