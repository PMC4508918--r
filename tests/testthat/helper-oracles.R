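# Independent oracles and small builders shared across the test files.

# Trinomial point probability by direct factorial arithmetic (small n).
oracle_trinomial_pmf <- function(x1, x2, x3, p) {
  factorial(x1 + x2 + x3) / (factorial(x1) * factorial(x2) * factorial(x3)) *
    p[1]^x1 * p[2]^x2 * p[3]^x3
}

# Expected cohort delta under the founding model: autosomal expectation is
# the sex-average of the founding proportions; the X expectation follows
# the recursion  x_f(t) = (x_f(t-1) + x_m(t-1)) / 2,  x_m(t) = x_f(t-1)
# (males receive only maternal X), pooled over the cohort's X copies.
oracle_delta_truth <- function(props_m, props_f, n_m, n_f, n_gen,
                               chrom_lengths, x_chrom = "chrX") {
  f_auto <- (props_m + props_f) / 2
  x_f <- props_f
  x_m <- props_m
  for (g in seq_len(n_gen)) {
    x_f_new <- (x_f + x_m) / 2
    x_m <- x_f
    x_f <- x_f_new
  }
  f_x <- (2 * n_f * x_f + n_m * x_m) / (2 * n_f + n_m)
  la <- sum(chrom_lengths[names(chrom_lengths) != x_chrom])
  lx <- chrom_lengths[[x_chrom]]
  w_auto <- la * 2 * (n_m + n_f)
  w_x <- lx * (2 * n_f + n_m)
  f_total <- (f_auto * w_auto + f_x * w_x) / (w_auto + w_x)
  list(delta = (f_x - f_auto) / f_total,
       f_auto = f_auto, f_x = f_x, f_total = f_total)
}

# Ancestry-fraction records for synthetic cohorts built directly from
# per-individual fraction matrices (rows = individuals, cols AFR/NAM/EUR).
make_asym_records <- function(f_auto, f_x, len_auto = 2e9, len_x = 1.5e8) {
  n <- nrow(f_auto)
  ids <- sprintf("s%03d", seq_len(n))
  rows <- list()
  for (i in seq_len(n)) {
    tot <- (f_auto[i, ] * len_auto + f_x[i, ] * len_x) / (len_auto + len_x)
    rows[[length(rows) + 1]] <- data.frame(
      individual = ids[i], sex = NA_character_,
      compartment = c("auto", "X", "total"),
      len = c(len_auto, len_x, len_auto + len_x),
      AFR = c(f_auto[i, 1], f_x[i, 1], tot[1]),
      NAM = c(f_auto[i, 2], f_x[i, 2], tot[2]),
      EUR = c(f_auto[i, 3], f_x[i, 3], tot[3]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Random points on the probability simplex.
rand_simplex <- function(n, concentration = 1) {
  x <- matrix(stats::rgamma(3 * n, concentration), n, 3)
  x / rowSums(x)
}

# Segment data frame where each haplotype has one ancestry per fixed-width
# window: `anc` is an n_hap x n_window matrix of labels (or NA for a
# coverage gap); haplotypes are paired into diploid individuals.
segments_from_matrix <- function(anc, window_size = 1000, chrom = "chr1") {
  rows <- list()
  n_hap <- nrow(anc)
  for (h in seq_len(n_hap)) {
    for (w in seq_len(ncol(anc))) {
      if (is.na(anc[h, w])) next
      rows[[length(rows) + 1]] <- data.frame(
        individual = sprintf("d%03d", ceiling(h / 2)),
        haplotype = (h - 1) %% 2, chrom = chrom,
        start = (w - 1) * window_size, end = w * window_size,
        ancestry = anc[h, w], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Fuzzed valid segment table spanning several individuals/chromosomes,
# with optional coverage gaps.
fuzz_segments <- function(seed, n_ind = 4, chroms = c(chr1 = 5e6, chr2 = 3e6),
                          gap_prob = 0.2) {
  with_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(s); on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_ind)) {
      for (cc in names(chroms)) {
        for (h in 0:1) {
          cuts <- sort(unique(c(0, chroms[[cc]],
                                sample.int(chroms[[cc]] - 1, sample(1:6, 1)))))
          for (k in seq_len(length(cuts) - 1)) {
            if (stats::runif(1) < gap_prob) next
            rows[[length(rows) + 1]] <- data.frame(
              individual = sprintf("f%02d", i), haplotype = h, chrom = cc,
              start = cuts[k], end = cuts[k + 1],
              ancestry = sample(ANCESTRIES, 1), stringsAsFactors = FALSE)
          }
        }
      }
    }
    df <- do.call(rbind, rows)
    df[order(df$individual, df$haplotype, df$chrom, df$start), ]
  })
}

fixture_path <- function(...) {
  system.file("extdata", "sim12", ..., package = "admixscan")
}
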