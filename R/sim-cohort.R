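# Forward simulator of admixed diploid cohorts.
#
# Internal haplotype representation: a "tract object" is a list with
#   end : numeric vector of tract end positions (0-based half-open; the
#         last end equals the chromosome length)
#   anc : integer ancestry codes (1 = AFR, 2 = NAM, 3 = EUR)
# Starts are implicit (0, then the previous end), so tracts tile the
# chromosome with no gaps or overlaps by construction.

tr_make <- function(end, anc) list(end = as.numeric(end), anc = as.integer(anc))

tr_merge <- function(h) {
  k <- length(h$anc)
  if (k <= 1L) return(h)
  keep <- c(h$anc[-1L] != h$anc[-k], TRUE)
  list(end = h$end[keep], anc = h$anc[keep])
}

# Extract [lo, hi) from tract object h.
tr_slice <- function(h, lo, hi) {
  i0 <- sum(h$end <= lo) + 1L
  i1 <- sum(h$end < hi) + 1L
  end <- h$end[i0:i1]
  end[length(end)] <- hi
  list(end = end, anc = h$anc[i0:i1])
}

tr_to_df <- function(h) {
  data.frame(start = c(0, h$end[-length(h$end)]), end = h$end,
             ancestry = ANCESTRIES[h$anc], stringsAsFactors = FALSE)
}

df_to_tr <- function(df) {
  o <- order(df$start)
  tr_make(df$end[o], match(df$ancestry[o], ANCESTRIES))
}

check_tiling_df <- function(df, chrom_length) {
  o <- order(df$start)
  s <- df$start[o]; e <- df$end[o]
  if (length(s) == 0 || s[1] != 0 || abs(e[length(e)] - chrom_length) > 0 ||
      any(e <= s) || (length(s) > 1 && any(s[-1] != e[-length(e)])))
    stop_param("parent haplotype tracts must tile [0, chrom_length)")
  invisible(TRUE)
}

# Core meiosis: Poisson crossovers, uniform breakpoints, random start
# haplotype; adjacent same-ancestry pieces merged.
gamete_core <- function(h1, h2, chrom_length, recomb_rate) {
  n_x <- stats::rpois(1L, recomb_rate * chrom_length / 1e8)
  s <- sample.int(2L, 1L)
  parents <- list(h1, h2)
  if (n_x == 0L) return(parents[[s]])
  bp <- sort(unique(stats::runif(n_x, 0, chrom_length)))
  cuts <- c(0, bp, chrom_length)
  src <- rep_len(c(s, 3L - s), length(cuts) - 1L)
  end <- numeric(0); anc <- integer(0)
  for (i in seq_len(length(cuts) - 1L)) {
    p <- tr_slice(parents[[src[i]]], cuts[i], cuts[i + 1L])
    end <- c(end, p$end); anc <- c(anc, p$anc)
  }
  tr_merge(list(end = end, anc = anc))
}

#' Ancestral allele frequencies under the Balding-Nichols model
#'
#' Draws, for each SNP, an ancestral base frequency uniform on (0.05, 0.95)
#' and three diverged population frequencies from independent
#' Beta(p(1-F)/F, (1-p)(1-F)/F) distributions, whose variance around the
#' base frequency is F p (1 - p). Larger F produces more
#' population-enriched alleles.
#'
#' @param n_snps Number of SNPs (>= 1).
#' @param fst_divergence Divergence F in (0, 1).
#' @param seed Integer seed.
#' @return Data frame with columns `base`, `AFR`, `NAM`, `EUR`; all
#'   frequencies strictly inside (0, 1).
#' @export
generate_allele_freqs <- function(n_snps, fst_divergence, seed = 1L) {
  if (!is.numeric(n_snps) || length(n_snps) != 1L || n_snps < 1)
    stop_param("n_snps must be >= 1")
  if (!is.numeric(fst_divergence) || length(fst_divergence) != 1L ||
      !is.finite(fst_divergence) || fst_divergence <= 0 ||
      fst_divergence >= 1)
    stop_param("fst_divergence must be a finite value in (0, 1)")
  n_snps <- as.integer(n_snps)
  f <- fst_divergence
  with_seed(seed, {
    p0 <- stats::runif(n_snps, 0.05, 0.95)
    a <- p0 * (1 - f) / f
    b <- (1 - p0) * (1 - f) / f
    out <- data.frame(base = p0,
                      AFR = stats::rbeta(n_snps, a, b),
                      NAM = stats::rbeta(n_snps, a, b),
                      EUR = stats::rbeta(n_snps, a, b))
    for (col in ANCESTRIES)
      out[[col]] <- pmin(pmax(out[[col]], 1e-12), 1 - 1e-12)
    out
  })
}

#' Simulate one meiotic gamete from a pair of parental haplotypes
#'
#' Crossover count is Poisson with mean `recomb_rate * length / 1e8`,
#' breakpoints are uniform, and the gamete alternates between the two
#' parental haplotypes starting from one chosen with probability 1/2.
#' On the X chromosome a male parent transmits his single X intact, and
#' only to daughters; asking for a paternal X gamete destined to a son is
#' an error.
#'
#' @param hap1,hap2 Parental haplotypes as data frames with columns
#'   `start`, `end`, `ancestry`, tiling `[0, chrom_length)`. For a male
#'   parent's X, `hap2` may be `NULL`.
#' @param chrom_length Chromosome length in bp.
#' @param recomb_rate Crossovers per 1e8 bp.
#' @param chrom Chromosome name; `"chrX"` triggers the X transmission
#'   rules.
#' @param parent_sex `"M"` or `"F"`.
#' @param child_sex `"M"` or `"F"`; only consulted for a male parent's X.
#' @return Gamete haplotype as a `start`/`end`/`ancestry` data frame with
#'   adjacent same-ancestry tracts merged.
#' @export
recombine_gamete <- function(hap1, hap2, chrom_length, recomb_rate = 1.2,
                             chrom = "chr1", parent_sex = "F",
                             child_sex = "F") {
  check_tiling_df(hap1, chrom_length)
  if (identical(chrom, "chrX") && parent_sex == "M") {
    if (identical(child_sex, "M"))
      stop_param("sons receive no paternal X chromosome")
    return(tr_to_df(tr_merge(df_to_tr(hap1))))
  }
  check_tiling_df(hap2, chrom_length)
  g <- gamete_core(df_to_tr(hap1), df_to_tr(hap2), chrom_length, recomb_rate)
  tr_to_df(g)
}

#' Forward-simulate an admixed diploid cohort
#'
#' Generation 0 founders are unadmixed: each founder haplotype receives a
#' single ancestry, drawn once per haplotype from the founder proportions
#' of the founder's sex and shared across all chromosomes (a founder
#' haplotype descends from one population). Each later generation is
#' produced by random mating (fathers and mothers drawn independently with
#' replacement, non-overlapping generations, constant population size).
#' Autosomes and the maternal X recombine per [recombine_gamete()]; sons
#' receive only a maternal X, daughters the paternal X intact plus a
#' maternal recombinant. Males carry a single X haplotype recorded with
#' haplotype index 0.
#'
#' @param config A [cohort_sim_config()].
#' @param out_dir Optional directory; when given, segments
#'   (`segments.tsv`), genotypes (`genotypes.vcf`), allele frequencies
#'   (`allele_freqs.tsv`) and the truth table (`truth.tsv`) are written
#'   there.
#' @param genotypes If `FALSE`, skip SNP genotype simulation.
#' @return An object of class `sim_cohort`: list with elements `config`,
#'   `ids`, `sexes` (named `"M"`/`"F"` vector), `segments` (ancestry
#'   segment data frame), `truth` (per-individual ancestry fractions by
#'   compartment, from tract lengths), `freqs` (allele-frequency table)
#'   and `genotypes` (a genotype matrix, see [sample_genotypes()]).
#' @export
simulate_pedigree_cohort <- function(config, out_dir = NULL,
                                     genotypes = TRUE) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n_individuals
  chroms <- names(config$chrom_lengths)
  lens <- config$chrom_lengths
  rate <- config$recomb_rate
  sexes <- c(rep("M", config$n_male), rep("F", n - config$n_male))
  props <- list(M = config$founder_props_male, F = config$founder_props_female)

  pop <- with_seed(substream_seed(config$seed, "pedigree"), {
    # founders
    pop <- vector("list", n)
    for (i in seq_len(n)) {
      lab <- c(sample.int(3L, 1L, prob = props[[sexes[i]]]),
               sample.int(3L, 1L, prob = props[[sexes[i]]]))
      haps <- lapply(chroms, function(cc) {
        if (cc == "chrX" && sexes[i] == "M")
          list(tr_make(lens[[cc]], lab[1L]))
        else
          list(tr_make(lens[[cc]], lab[1L]), tr_make(lens[[cc]], lab[2L]))
      })
      names(haps) <- chroms
      pop[[i]] <- haps
    }
    males <- which(sexes == "M"); females <- which(sexes == "F")
    for (g in seq_len(config$n_generations)) {
      fathers <- sample(males, n, replace = TRUE)
      mothers <- sample(females, n, replace = TRUE)
      nxt <- vector("list", n)
      for (i in seq_len(n)) {
        fa <- pop[[fathers[i]]]; mo <- pop[[mothers[i]]]
        haps <- vector("list", length(chroms))
        names(haps) <- chroms
        for (cc in chroms) {
          if (cc == "chrX") {
            mat <- gamete_core(mo[[cc]][[1L]], mo[[cc]][[2L]], lens[[cc]],
                               rate)
            haps[[cc]] <- if (sexes[i] == "M") list(mat)
                          else list(fa[[cc]][[1L]], mat)
          } else {
            pat <- gamete_core(fa[[cc]][[1L]], fa[[cc]][[2L]], lens[[cc]],
                               rate)
            mat <- gamete_core(mo[[cc]][[1L]], mo[[cc]][[2L]], lens[[cc]],
                               rate)
            haps[[cc]] <- list(pat, mat)
          }
        }
        nxt[[i]] <- haps
      }
      pop <- nxt
    }
    pop
  })

  ids <- sprintf("ind%0*d", max(2L, nchar(n)), seq_len(n))
  names(sexes) <- ids

  seg_list <- list()
  for (i in seq_len(n)) {
    for (cc in chroms) {
      for (h in seq_along(pop[[i]][[cc]])) {
        df <- tr_to_df(pop[[i]][[cc]][[h]])
        df$individual <- ids[i]
        df$haplotype <- h - 1L
        df$chrom <- cc
        seg_list[[length(seg_list) + 1L]] <- df
      }
    }
  }
  segments <- do.call(rbind, seg_list)
  segments <- segments[, c("individual", "haplotype", "chrom", "start",
                           "end", "ancestry")]
  rownames(segments) <- NULL

  truth <- fractions_from_tracts(segments, lens, sexes)
  truth$source <- "tracts"

  out <- structure(list(config = config, ids = ids, sexes = sexes,
                        segments = segments, truth = truth,
                        freqs = NULL, genotypes = NULL),
                   class = "sim_cohort")

  if (isTRUE(genotypes)) {
    pos <- with_seed(substream_seed(config$seed, "positions"), {
      lapply(chroms, function(cc)
        sort(sample.int(lens[[cc]], config$n_snps_per_chrom)) - 1)
    })
    names(pos) <- chroms
    fr <- generate_allele_freqs(config$n_snps_per_chrom * length(chroms),
                                config$fst_divergence,
                                substream_seed(config$seed, "freqs"))
    out$freqs <- data.frame(chrom = rep(chroms, lengths(pos)),
                            pos = unlist(pos, use.names = FALSE),
                            ref = "A", alt = "G",
                            freq_AFR = fr$AFR, freq_NAM = fr$NAM,
                            freq_EUR = fr$EUR,
                            stringsAsFactors = FALSE)
    out$genotypes <- sample_genotypes(out, out$freqs,
                                      substream_seed(config$seed,
                                                     "genotypes"))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_segments(segments, file.path(out_dir, "segments.tsv"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(out$freqs))
      write_allele_freqs(out$freqs, file.path(out_dir, "allele_freqs.tsv"))
    if (!is.null(out$genotypes))
      write_genotypes_vcf(out$genotypes, file.path(out_dir, "genotypes.vcf"))
  }
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated admixed cohort: %d individuals, %d segments, %s SNPs\n",
    length(x$ids), nrow(x$segments),
    if (is.null(x$genotypes)) "no" else nrow(x$genotypes$snps)))
  invisible(x)
}

#' Draw SNP genotypes from simulated ancestry tracts
#'
#' Each haplotype's allele at a SNP is Bernoulli with the alternate-allele
#' frequency of the ancestral population covering that position; the
#' diploid dosage is the allele sum. Males are haploid on the X (dosage in
#' `{0, 1}`, ploidy recorded as 1).
#'
#' @param truth A `sim_cohort` object, or any list with elements
#'   `segments`, `ids` and `sexes`.
#' @param freqs Allele-frequency table with columns `chrom`, `pos`,
#'   `freq_AFR`, `freq_NAM`, `freq_EUR` (see [read_allele_freqs()]).
#' @param seed Integer seed.
#' @return A genotype matrix object: list with `samples`, `snps`
#'   (chrom/pos/ref/alt), `dosage` (SNP x sample integer matrix) and
#'   `ploidy` (same shape; 1 marks hemizygous entries).
#' @export
sample_genotypes <- function(truth, freqs, seed = 1L) {
  segments <- truth$segments
  ids <- truth$ids
  sexes <- truth$sexes
  n_snp <- nrow(freqs)
  dosage <- matrix(0L, n_snp, length(ids),
                   dimnames = list(NULL, ids))
  ploidy <- matrix(2L, n_snp, length(ids), dimnames = list(NULL, ids))
  fmat <- as.matrix(freqs[, c("freq_AFR", "freq_NAM", "freq_EUR")])
  with_seed(seed, {
    for (cc in unique(freqs$chrom)) {
      rows <- which(freqs$chrom == cc)
      p <- freqs$pos[rows]
      segc <- segments[segments$chrom == cc, ]
      if (cc == "chrX") ploidy[rows, sexes[ids] == "M"] <- 1L
      for (i in seq_along(ids)) {
        si <- segc[segc$individual == ids[i], ]
        for (h in sort(unique(si$haplotype))) {
          sh <- si[si$haplotype == h, ]
          o <- order(sh$start)
          starts <- sh$start[o]; ends <- sh$end[o]
          anc <- match(sh$ancestry[o], ANCESTRIES)
          j <- findInterval(p, starts)
          if (any(j == 0) || any(p >= ends[pmax(j, 1L)]))
            stop_param("SNP position not covered by any ancestry tract (",
                       cc, ")")
          f <- fmat[cbind(rows, anc[j])]
          dosage[rows, i] <- dosage[rows, i] +
            as.integer(stats::runif(length(p)) < f)
        }
      }
    }
  })
  structure(list(samples = ids,
                 snps = freqs[, c("chrom", "pos", "ref", "alt")],
                 dosage = dosage, ploidy = ploidy),
            class = "genotype_matrix")
}

#' Tile chromosomes into locus windows
#'
#' Synthetic stand-in for recombination-map derived locus boundaries:
#' fixed-width half-open windows covering each chromosome.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_size Window width in bp.
#' @return Locus-window data frame (`chrom`, `start`, `end`, `locus_id`).
#' @export
make_locus_windows <- function(chrom_lengths, window_size = 1e6) {
  stopifnot(window_size > 0)
  pieces <- lapply(names(chrom_lengths), function(cc) {
    L <- chrom_lengths[[cc]]
    s <- seq(0, L - 1, by = window_size)
    data.frame(chrom = cc, start = s, end = pmin(s + window_size, L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$locus_id <- sprintf("L%06d", seq_len(nrow(out)))
  out
}
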