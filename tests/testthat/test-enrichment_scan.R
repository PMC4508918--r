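p_clm <- c(AFR = 0.073, NAM = 0.181, EUR = 0.746)

test_that("population-average proportions pool the per-locus counts", {
  cnt <- data.frame(x_AFR = c(1, 1), x_NAM = c(1, 1), x_EUR = c(2, 2),
                    n = c(4, 4))
  expect_equal(population_average_proportions(cnt),
               c(AFR = 0.25, NAM = 0.25, EUR = 0.5))
  cnt_eur <- data.frame(x_AFR = 0, x_NAM = 0, x_EUR = c(10, 10), n = 10)
  expect_equal(population_average_proportions(cnt_eur),
               c(AFR = 0, NAM = 0, EUR = 1))
  expect_equal(sum(population_average_proportions(cnt)), 1)
  expect_error(population_average_proportions(
    data.frame(x_AFR = 0, x_NAM = 0, x_EUR = 0, n = 0)), "no observed")
})

test_that("locus counts assign ancestry at the window midpoint", {
  # one fully-EUR diploid individual, one window
  seg <- segments_from_matrix(matrix("EUR", 2, 1))
  w <- data.frame(chrom = "chr1", start = 0, end = 1000, locus_id = "L1")
  cnt <- locus_counts(seg, w)
  expect_equal(unlist(cnt[, c("x_AFR", "x_NAM", "x_EUR", "n")],
                      use.names = FALSE), c(0, 0, 2, 2))

  # a boundary exactly at the midpoint: the right-hand (half-open
  # containing) segment wins
  seg2 <- data.frame(individual = "d001", haplotype = 0, chrom = "chr1",
                     start = c(0, 500), end = c(500, 1000),
                     ancestry = c("AFR", "EUR"))
  cnt2 <- locus_counts(seg2, w)
  expect_equal(cnt2$x_EUR, 1)
  expect_equal(cnt2$x_AFR, 0)

  # full coverage: every autosomal locus counts every chromosome copy
  set.seed(1)
  anc <- matrix(sample(ANCESTRIES, 12 * 6, TRUE), 12, 6)
  seg3 <- segments_from_matrix(anc)
  w3 <- make_locus_windows(c(chr1 = 6000), 1000)
  cnt3 <- locus_counts(seg3, w3)
  expect_equal(cnt3$n, rep(12, 6))
  expect_equal(cnt3$x_AFR, colSums(anc == "AFR"))

  # a coverage gap lowers the denominator; an uncovered chromosome is
  # flagged with n = 0
  anc_gap <- anc; anc_gap[3, 2] <- NA
  cnt4 <- locus_counts(segments_from_matrix(anc_gap), w3)
  expect_equal(cnt4$n[2], 11)
  w4 <- rbind(w3, data.frame(chrom = "chr9", start = 0, end = 1000,
                             locus_id = "L9"))
  cnt5 <- locus_counts(segments_from_matrix(anc), w4)
  expect_equal(cnt5$n[cnt5$chrom == "chr9"], 0)

  # X windows are kept apart from the autosomal scan
  segx <- seg2; segx$chrom <- "chrX"
  wx <- w; wx$chrom <- "chrX"
  expect_equal(nrow(locus_counts(segx, rbind(w, wx), "X")), 1)
})

test_that("trinomial probabilities match factorial and log-gamma oracles", {
  expect_equal(trinomial_pmf(5, 0, 0, c(1, 0, 0)), 1)
  # direct factorial arithmetic
  expect_equal(trinomial_pmf(2, 1, 1, c(0.5, 0.25, 0.25)),
               oracle_trinomial_pmf(2, 1, 1, c(0.5, 0.25, 0.25)))
  expect_equal(trinomial_pmf(2, 1, 1, c(0.5, 0.25, 0.25)), 0.1875)
  set.seed(2)
  for (r in 1:20) {
    p <- as.vector(rand_simplex(1))
    x <- as.vector(stats::rmultinom(1, sample(1:8, 1), p))
    expect_equal(trinomial_pmf(x[1], x[2], x[3], p),
                 oracle_trinomial_pmf(x[1], x[2], x[3], p))
  }
  # an all-European locus in a 120-chromosome cohort at the published
  # average proportions: log10 pmf = 120 * log10(0.746) ~ -15.3
  lp <- log10(trinomial_pmf(0, 0, 120, p_clm))
  expect_equal(lp, 120 * log10(0.746), tolerance = 1e-10)
  expect_equal(lp, -15.3, tolerance = 0.05)
  # impossible category
  expect_equal(trinomial_pmf(1, 0, 4, c(0, 0.5, 0.5)), 0)
  expect_error(trinomial_pmf(-1, 0, 4, p_clm), "non-negative")

  # normalization over all compositions (small n here; the full check
  # runs in the acceptance suite)
  set.seed(3)
  for (n in c(1, 5, 12)) {
    p <- as.vector(rand_simplex(1))
    x1 <- rep(0:n, times = (n + 1):1)
    x2 <- unlist(lapply(0:n, function(a) 0:(n - a)))
    expect_equal(sum(trinomial_pmf(x1, x2, n - x1 - x2, p)), 1,
                 tolerance = 1e-12)
  }
})

test_that("the exact multinomial tail enumerates by point probability", {
  # hand enumeration at n = 2: outcomes with pmf <= 0.0625 are (0,2,0)
  # and (0,0,2)
  expect_equal(exact_multinomial_tail(0, 2, 0, c(0.5, 0.25, 0.25)), 0.125)
  # the modal composition has tail probability 1
  n <- 120
  x1 <- rep(0:n, times = (n + 1):1)
  x2 <- unlist(lapply(0:n, function(a) 0:(n - a)))
  pmf_all <- trinomial_pmf(x1, x2, n - x1 - x2, p_clm)
  mode_i <- which.max(pmf_all)
  expect_equal(exact_multinomial_tail(x1[mode_i], x2[mode_i],
                                      n - x1[mode_i] - x2[mode_i], p_clm),
               1, tolerance = 1e-12)
  # tail >= pmf everywhere; ties included
  set.seed(4)
  for (r in 1:10) {
    p <- as.vector(rand_simplex(1))
    x <- as.vector(stats::rmultinom(1, 40, p))
    tp <- exact_multinomial_tail(x[1], x[2], x[3], p)
    expect_gte(tp, trinomial_pmf(x[1], x[2], x[3], p) * (1 - 1e-12))
    expect_lte(tp, 1)
  }
  # Monte-Carlo cross-check on a modest case
  set.seed(5)
  p <- c(0.2, 0.3, 0.5)
  x <- c(10, 6, 14)
  tp <- exact_multinomial_tail(x[1], x[2], x[3], p)
  draws <- stats::rmultinom(100000, 30, p)
  pmf_obs <- trinomial_pmf(x[1], x[2], x[3], p)
  pmf_draws <- trinomial_pmf(draws[1, ], draws[2, ], draws[3, ], p)
  mc <- mean(pmf_draws <= pmf_obs * (1 + 1e-9))
  expect_lt(abs(mc - tp), 4 * sqrt(tp * (1 - tp) / 100000))
  expect_error(exact_multinomial_tail(20000, 0, 0, p), "too large")
})

test_that("BH q-values implement the step-up rule", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.007), 0.007)
  set.seed(6)
  for (r in 1:5) {
    p <- runif(50)^2
    q <- bh_qvalues(p)
    # independent route: stats::p.adjust
    expect_equal(q, stats::p.adjust(p, "BH"))
    # monotone in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_qvalues(c(0.1, NaN)), "finite")
  expect_error(bh_qvalues(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("log-fold enrichment compares observed to expected counts", {
  cnt <- data.frame(x_AFR = 30, x_NAM = 20, x_EUR = 70, n = 120)
  lf <- logfold_enrichment(cnt, p_clm)
  expect_equal(unname(lf[1, "lf_AFR"]), log2(30 / (120 * 0.073)))
  expect_equal(unname(lf[1, "lf_AFR"]), 1.776, tolerance = 0.001)
  # exactly at expectation -> 0; doubled -> +1; absent -> -Inf
  e <- data.frame(x_AFR = 12, x_NAM = 24, x_EUR = 84, n = 120)
  expect_equal(unname(logfold_enrichment(e, c(0.1, 0.2, 0.7))[1, ]),
               c(0, 0, 0))
  d2 <- data.frame(x_AFR = 24, x_NAM = 12, x_EUR = 84, n = 120)
  expect_equal(unname(logfold_enrichment(d2, c(0.1, 0.2, 0.7))[1, 1]), 1)
  z <- data.frame(x_AFR = 0, x_NAM = 36, x_EUR = 84, n = 120)
  expect_equal(unname(logfold_enrichment(z, c(0.1, 0.2, 0.7))[1, 1]), -Inf)
})

test_that("the genome scan flags injected anomalies and is deterministic", {
  # 60 diploid individuals over 40 windows drawn near the expected
  # proportions, with one window forced entirely African
  set.seed(7)
  n_hap <- 120; n_win <- 40
  anc <- matrix(sample(ANCESTRIES, n_hap * n_win, TRUE,
                       prob = p_clm), n_hap, n_win)
  anc[, 13] <- "AFR"
  seg <- segments_from_matrix(anc)
  w <- make_locus_windows(c(chr1 = n_win * 1000), 1000)
  sc <- scan_genome(seg, w, alpha_p = 1e-9, score = "pmf",
                    expected = p_clm)
  expect_true(sc$significant[13])
  expect_equal(sc$enriched_ancestry[13], "AFR")
  expect_equal(sc$depleted_ancestry[13], "EUR")
  expect_lt(log10(sc$pmf_score[13]), -9)
  # both scores are reported and ordered: pmf <= exact tail
  expect_true(all(sc$pmf_score <= sc$tail_p + 1e-12))
  # determinism
  sc2 <- scan_genome(seg, w, alpha_p = 1e-9, score = "pmf",
                     expected = p_clm)
  expect_identical(as.data.frame(sc), as.data.frame(sc2))
  # expected proportions default to the pooled counts of the scan itself
  sc3 <- scan_genome(seg, w)
  expect_equal(unname(attr(sc3, "expected")),
               unname(population_average_proportions(
                 locus_counts(seg, w))))
})

test_that("combination frequencies form a proper distribution", {
  cnt <- data.frame(x_AFR = c(2, 2, 5), x_NAM = c(3, 3, 0),
                    x_EUR = c(7, 7, 7), n = 12)
  g <- combination_frequency_grid(cnt)
  expect_equal(sum(g$frequency), 1)
  expect_equal(g$frequency[g$x_AFR == 2 & g$x_NAM == 3], 2 / 3)
  one <- combination_frequency_grid(cnt[1:2, ])
  expect_equal(nrow(one), 1)
  expect_equal(one$frequency, 1)
  two <- combination_frequency_grid(cnt[c(1, 3), ])
  expect_equal(two$frequency, c(0.5, 0.5))
  # heterogeneous totals fall back to a fixed proportion grid
  het <- data.frame(x_AFR = c(2, 1), x_NAM = c(2, 1), x_EUR = c(4, 2),
                    n = c(8, 4))
  gh <- combination_frequency_grid(het)
  expect_equal(attr(gh, "mode"), "proportions")
  expect_equal(nrow(gh), 1)  # identical proportions share a bin
  expect_equal(sum(gh$frequency), 1)
})

test_that("significant loci merge by adjacency and ancestry", {
  base <- data.frame(chrom = "chr1", start = (0:5) * 1000,
                     end = (1:6) * 1000,
                     locus_id = sprintf("L%d", 1:6),
                     score = 1e-12, significant = TRUE,
                     enriched_ancestry = "EUR",
                     stringsAsFactors = FALSE)
  base$score <- c(1e-12, 1e-15, 0.5, 1e-11, 1e-11, 1e-10)
  base$significant <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  base$enriched_ancestry <- c("EUR", "EUR", NA, "AFR", "AFR", "EUR")
  m <- merge_significant_segments(base)
  expect_equal(nrow(m), 3)
  expect_equal(m$end[1], 2000)        # two adjacent EUR loci merge
  expect_equal(m$min_p[1], 1e-15)
  expect_equal(m$ancestry[2], "AFR")  # ancestry change breaks the run
  expect_equal(m$n_loci[3], 1)        # isolated locus stays alone
  expect_equal(nrow(merge_significant_segments(base[base$score > 1, ])), 0)
})

test_that("gene annotation uses half-open overlap", {
  segs <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  genes <- data.frame(chrom = "chr1",
                      start = c(1200, 2000, 500, 1900, 1100),
                      end = c(1300, 2100, 1000, 2500, 1250),
                      name = c("INSIDE", "ABUT", "BEFORE", "SPAN", "ALSO"),
                      stringsAsFactors = FALSE)
  ann <- annotate_genes(segs, genes)
  # abutting [2000,2100) does not overlap [1000,2000); names sorted by
  # gene start
  expect_equal(ann$genes, "ALSO,INSIDE,SPAN")
  expect_equal(annotate_genes(segs, genes[3, ])$genes, "")
})
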