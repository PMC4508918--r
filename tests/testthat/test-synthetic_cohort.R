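test_that("Balding-Nichols frequencies are reproducible and scale with F", {
  # same seed -> identical table; different seed -> different draws
  f1 <- generate_allele_freqs(500, 0.15, seed = 7)
  f2 <- generate_allele_freqs(500, 0.15, seed = 7)
  f3 <- generate_allele_freqs(500, 0.15, seed = 8)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))

  # degenerate limit: F -> 0 collapses onto the shared base frequency
  f0 <- generate_allele_freqs(2000, 1e-5, seed = 1)
  expect_lt(max(abs(as.matrix(f0[, ANCESTRIES]) - f0$base)), 0.05)

  # F = 0.15: mean pairwise |difference| between populations sits in the
  # band implied by Var = F p (1 - p)
  fr <- generate_allele_freqs(10000, 0.15, seed = 2)
  d <- mean(c(abs(fr$AFR - fr$NAM), abs(fr$AFR - fr$EUR),
              abs(fr$NAM - fr$EUR)))
  expect_gt(d, 0.1)
  expect_lt(d, 0.3)

  expect_error(generate_allele_freqs(100, 0), "fst_divergence")
  expect_error(generate_allele_freqs(100, 1), "fst_divergence")
  expect_error(generate_allele_freqs(100, NA), "fst_divergence")
  expect_error(generate_allele_freqs(0, 0.1), "n_snps")
})

test_that("meiosis respects parental material and the X transmission rules", {
  L <- 1e7
  h_eur <- data.frame(start = 0, end = L, ancestry = "EUR")
  h_mix <- data.frame(start = c(0, 4e6), end = c(4e6, L),
                      ancestry = c("AFR", "NAM"))

  # zero recombination: the gamete is one parent, chosen fairly
  set.seed(1)
  picks <- replicate(200, {
    g <- recombine_gamete(h_eur, h_mix, L, recomb_rate = 0)
    identical(g$ancestry, "EUR")
  })
  expect_gt(mean(picks), 0.35)
  expect_lt(mean(picks), 0.65)

  # invariance: two all-EUR parents give an all-EUR gamete whatever the
  # crossover count
  set.seed(2)
  for (r in c(5, 50)) {
    g <- recombine_gamete(h_eur, h_eur, L, recomb_rate = r)
    expect_identical(g$ancestry, "EUR")
    expect_equal(g$start, 0)
    expect_equal(g$end, L)
  }

  # conservation: at any position the gamete carries one of the two
  # parental ancestries present there
  set.seed(3)
  anc_at <- function(h, pos) h$ancestry[findInterval(pos, h$start)]
  for (rep in 1:25) {
    cuts <- sort(unique(c(0, L, sample.int(L - 1, 5))))
    h2 <- data.frame(start = cuts[-length(cuts)], end = cuts[-1],
                     ancestry = sample(ANCESTRIES, length(cuts) - 1,
                                       replace = TRUE))
    g <- recombine_gamete(h_mix, h2, L, recomb_rate = 3)
    pos <- runif(20, 0, L)
    expect_true(all(anc_at(g, pos) == anc_at(h_mix, pos) |
                      anc_at(g, pos) == anc_at(h2, pos)))
  }

  # X rules: a father's X goes intact to daughters and never to sons
  expect_identical(
    recombine_gamete(h_mix, NULL, L, chrom = "chrX", parent_sex = "M",
                     child_sex = "F"),
    h_mix)
  expect_error(
    recombine_gamete(h_mix, NULL, L, chrom = "chrX", parent_sex = "M",
                     child_sex = "M"),
    "sons")

  # malformed parents are rejected
  bad <- data.frame(start = c(0, 6e6), end = c(4e6, L),
                    ancestry = c("AFR", "EUR"))
  expect_error(recombine_gamete(bad, h_eur, L), "tile")
})

test_that("crossover counts match the Poisson mean", {
  L <- 1e8
  rate <- 2
  h1 <- data.frame(start = 0, end = L, ancestry = "AFR")
  h2 <- data.frame(start = 0, end = L, ancestry = "EUR")
  set.seed(42)
  # parents differ everywhere, so every crossover is a visible boundary
  n_bp <- replicate(4000, nrow(recombine_gamete(h1, h2, L, rate)) - 1)
  se <- sqrt(rate * L / 1e8 / 4000)
  expect_lt(abs(mean(n_bp) - rate * L / 1e8), 3 * se)
})

test_that("F1 crosses obey the autosomal and X transmission identities", {
  cfg <- cohort_sim_config(
    n_individuals = 12, n_generations = 1,
    founder_props_male = c(0, 0, 1), founder_props_female = c(0, 1, 0),
    chrom_lengths = c(chr1 = 5e7, chr2 = 3e7, chrX = 4e7),
    n_snps_per_chrom = 50, seed = 9)
  sim <- simulate_pedigree_cohort(cfg, genotypes = FALSE)
  auto <- sim$truth[sim$truth$compartment == "auto", ]
  expect_equal(auto$AFR, rep(0, 12))
  expect_equal(auto$NAM, rep(0.5, 12))
  expect_equal(auto$EUR, rep(0.5, 12))
  xx <- sim$truth[sim$truth$compartment == "X", ]
  sons <- xx[xx$sex == "M", ]
  expect_equal(sons$NAM, rep(1, nrow(sons)))
  daughters <- xx[xx$sex == "F", ]
  expect_equal(daughters$NAM, rep(0.5, nrow(daughters)))
  expect_equal(daughters$EUR, rep(0.5, nrow(daughters)))

  expect_error(cohort_sim_config(n_individuals = 1), "n_individuals")
  expect_error(cohort_sim_config(n_generations = 0), "n_generations")
  expect_error(cohort_sim_config(founder_props_male = c(0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("simulated haplotypes tile their chromosomes exactly", {
  cfg <- cohort_sim_config(
    n_individuals = 10, n_generations = 4,
    chrom_lengths = c(chr1 = 4e7, chr2 = 2e7, chrX = 3e7),
    n_snps_per_chrom = 20, seed = 31)
  sim <- simulate_pedigree_cohort(cfg, genotypes = FALSE)
  seg <- sim$segments
  grp <- paste(seg$individual, seg$haplotype, seg$chrom)
  for (sub in split(seg, grp)) {
    o <- order(sub$start)
    expect_equal(sub$start[o][1], 0)
    expect_equal(sub$end[o][nrow(sub)], cfg$chrom_lengths[[sub$chrom[1]]])
    expect_true(all(sub$end[o] > sub$start[o]))
    if (nrow(sub) > 1) {
      expect_equal(sub$start[o][-1], sub$end[o][-nrow(sub)])
      # merged representation: no two adjacent tracts share an ancestry
      expect_true(all(sub$ancestry[o][-1] != sub$ancestry[o][-nrow(sub)]))
    }
  }
  # males carry one X haplotype, females two
  xseg <- seg[seg$chrom == "chrX", ]
  nhap <- tapply(xseg$haplotype, xseg$individual,
                 function(h) length(unique(h)))
  expect_true(all(nhap[sim$sexes[names(nhap)] == "M"] == 1))
  expect_true(all(nhap[sim$sexes[names(nhap)] == "F"] == 2))
  # same seed reproduces the cohort byte-for-byte
  sim2 <- simulate_pedigree_cohort(cfg, genotypes = FALSE)
  expect_identical(sim$segments, sim2$segments)
})

test_that("cohort-mean fractions are unbiased for the founding proportions", {
  # 40 replicate cohorts at the default scale; the Monte-Carlo SE of the
  # mean autosomal fraction is ~0.007 per component, so a 0.02 band is a
  # ~3-sigma unbiasedness check
  reps <- 40
  target <- (c(AFR = 0.073, NAM = 0, EUR = 0.927) +
               c(0.073, 0.362, 0.565)) / 2
  means <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    sim <- simulate_pedigree_cohort(cohort_sim_config(seed = 1000 + r),
                                    genotypes = FALSE)
    auto <- sim$truth[sim$truth$compartment == "auto", ]
    means[r, ] <- colMeans(as.matrix(auto[, ANCESTRIES]))
  }
  bias <- colMeans(means) - target
  expect_true(all(abs(bias) < 0.02))
})

test_that("sex-biased founding leaves the prescribed X-autosome signature", {
  # European-skewed fathers, Native-American-skewed mothers: the X should
  # carry more NAM than the autosomes in >= 19/20 replicate cohorts
  reps <- 20
  ok <- logical(reps)
  for (r in seq_len(reps)) {
    cfg <- cohort_sim_config(
      n_individuals = 100, n_generations = 3,
      founder_props_male = c(0.05, 0, 0.95),
      founder_props_female = c(0.05, 0.65, 0.30),
      seed = 7000 + r)
    sim <- simulate_pedigree_cohort(cfg, genotypes = FALSE)
    arr <- admixscan:::records_arrays(sim$truth)
    idx <- seq_along(arr$ids)
    nam_x <- sum(arr$X$w[idx, "NAM"]) / sum(arr$X$len[idx])
    nam_auto <- sum(arr$auto$w[idx, "NAM"]) / sum(arr$auto$len[idx])
    ok[r] <- nam_x > nam_auto
  }
  expect_gte(sum(ok), 19)
})

test_that("genotype sampling follows the tract-conditional frequencies", {
  # all-zero frequencies force all-zero genotypes
  n <- 40
  seg <- data.frame(individual = rep(c("a", "b"), each = 2),
                    haplotype = c(0, 1, 0, 1), chrom = "chr1",
                    start = 0, end = 1e6,
                    ancestry = c("AFR", "EUR", "NAM", "EUR"))
  freqs0 <- data.frame(chrom = "chr1", pos = seq(0, 9e5, length.out = n),
                       ref = "A", alt = "G", freq_AFR = 0, freq_NAM = 0,
                       freq_EUR = 0)
  truth <- list(segments = seg, ids = c("a", "b"),
                sexes = c(a = "M", b = "F"))
  gm0 <- sample_genotypes(truth, freqs0, seed = 1)
  expect_true(all(gm0$dosage == 0))

  # an all-EUR diploid individual draws Binomial(2, f_EUR): pooled
  # chi-square goodness of fit over 5000 SNPs at alpha = 0.01
  seg1 <- data.frame(individual = "e", haplotype = 0:1, chrom = "chr1",
                     start = 0, end = 1e7, ancestry = "EUR")
  fr <- generate_allele_freqs(5000, 0.2, seed = 3)
  set.seed(5)
  freqs <- data.frame(chrom = "chr1",
                      pos = sort(sample.int(1e7, 5000)) - 1,
                      ref = "A", alt = "G", freq_AFR = fr$AFR,
                      freq_NAM = fr$NAM, freq_EUR = fr$EUR)
  gm <- sample_genotypes(list(segments = seg1, ids = "e",
                              sexes = c(e = "F")), freqs, seed = 11)
  f <- freqs$freq_EUR
  exp_cat <- c(sum((1 - f)^2), sum(2 * f * (1 - f)), sum(f^2))
  obs_cat <- tabulate(gm$dosage + 1, nbins = 3)
  chisq <- sum((obs_cat - exp_cat)^2 / exp_cat)
  expect_lt(chisq, qchisq(0.99, df = 2))

  # determinism and hemizygous X handling
  gm2 <- sample_genotypes(truth, freqs0, seed = 1)
  expect_identical(gm0, gm2)
  segx <- data.frame(individual = c("m", "m", "f", "f"),
                     haplotype = c(0, 0, 0, 1),
                     chrom = c("chr1", "chrX", "chrX", "chrX"),
                     start = 0, end = 1e6,
                     ancestry = c("EUR", "NAM", "NAM", "NAM"))
  freqx <- data.frame(chrom = c("chr1", "chrX"), pos = c(100, 100),
                      ref = "A", alt = "G", freq_AFR = 0.5, freq_NAM = 1,
                      freq_EUR = 0)
  gmx <- sample_genotypes(list(segments = segx, ids = c("m", "f"),
                               sexes = c(m = "M", f = "F")),
                          freqx, seed = 2)
  expect_equal(gmx$ploidy[2, ], c(m = 1L, f = 2L))
  expect_equal(gmx$dosage[2, ], c(m = 1L, f = 2L))

  # a SNP outside tract coverage is an internal consistency error
  freq_bad <- freqs0[1, ]
  freq_bad$pos <- 5e6
  expect_error(sample_genotypes(truth, freq_bad, seed = 1), "not covered")
})
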