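# Genome-wide ancestry-enrichment scan: per-locus three-way chromosome
# counts, the trinomial probability of the observed combination given the
# population-average ancestry proportions, an exact multinomial tail
# alternative, Benjamini-Hochberg FDR, log-fold enrichment, merging of
# significant segments and gene annotation.

#' Population-average ancestry proportions from locus counts
#'
#' Pools the per-locus chromosome counts: `p_k = sum(x_k) / sum(n)` over
#' all loci, so the expectation is derived from the same local-ancestry
#' calls being scanned.
#'
#' @param counts Locus-count data frame from [locus_counts()].
#' @return Named probability 3-vector (AFR, NAM, EUR) summing to 1.
#' @export
population_average_proportions <- function(counts) {
  tot <- sum(counts$n)
  if (is.na(tot) || tot == 0) stop_param("no observed chromosomes")
  p <- c(AFR = sum(counts$x_AFR), NAM = sum(counts$x_NAM),
         EUR = sum(counts$x_EUR)) / tot
  p
}

#' Per-locus ancestry chromosome counts
#'
#' Each haplotype contributes, at each locus window, the ancestry of the
#' segment covering the window midpoint (half-open containment, so a
#' segment boundary exactly at the midpoint assigns the right-hand
#' segment deterministically). Haplotypes with no covering segment reduce
#' the locus denominator `n`; males contribute a single X haplotype, so
#' X loci have `n <= 2 * n_females + n_males`.
#'
#' @param segments Validated segment data frame.
#' @param windows Locus-window data frame.
#' @param chrom_class `"autosome"` or `"X"`.
#' @param x_chrom Name of the X chromosome.
#' @return Data frame with `locus_id`, `chrom`, `start`, `end`, counts
#'   `x_AFR`, `x_NAM`, `x_EUR` and `n`. Windows on chromosomes absent
#'   from the segment calls keep `n = 0`.
#' @export
locus_counts <- function(segments, windows,
                         chrom_class = c("autosome", "X"),
                         x_chrom = "chrX") {
  chrom_class <- match.arg(chrom_class)
  w <- if (chrom_class == "X") windows[windows$chrom == x_chrom, ]
       else windows[windows$chrom != x_chrom, ]
  w <- w[order(match(w$chrom, chrom_order(w$chrom)), w$start), ]
  mid <- floor((w$start + w$end) / 2)
  cnt <- matrix(0L, nrow(w), 3, dimnames = list(NULL, ANCESTRIES))
  seg <- segments[segments$chrom %in% unique(w$chrom), ]
  if (nrow(seg)) {
    grp <- paste(seg$individual, seg$haplotype, seg$chrom, sep = "\r")
    for (sub in split(seg, grp)) {
      cc <- sub$chrom[1]
      wi <- which(w$chrom == cc)
      if (!length(wi)) next
      o <- order(sub$start)
      starts <- sub$start[o]; ends <- sub$end[o]
      anc <- match(sub$ancestry[o], ANCESTRIES)
      j <- findInterval(mid[wi], starts)
      hit <- j > 0 & mid[wi] < ends[pmax(j, 1L)]
      if (any(hit)) {
        ij <- cbind(wi[hit], anc[j[hit]])
        for (r in seq_len(nrow(ij)))
          cnt[ij[r, 1], ij[r, 2]] <- cnt[ij[r, 1], ij[r, 2]] + 1L
      }
    }
  }
  data.frame(locus_id = w$locus_id, chrom = w$chrom, start = w$start,
             end = w$end, x_AFR = cnt[, 1], x_NAM = cnt[, 2],
             x_EUR = cnt[, 3], n = rowSums(cnt), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Trinomial probability of an ancestry count combination
#'
#' `pmf = n! / (x1! x2! x3!) * p1^x1 * p2^x2 * p3^x3`, evaluated in log
#' space via log-gamma. A category with zero probability but a positive
#' count gives exactly 0.
#'
#' @param x1,x2,x3 Non-negative AFR/NAM/EUR chromosome counts
#'   (vectorised).
#' @param p Probability 3-vector summing to 1.
#' @return The point probability.
#' @export
trinomial_pmf <- function(x1, x2, x3, p) {
  exp(trinomial_logpmf(x1, x2, x3, p))
}

trinomial_logpmf <- function(x1, x2, x3, p) {
  if (any(c(x1, x2, x3) < 0)) stop_param("counts must be non-negative")
  x <- cbind(x1, x2, x3)
  n <- rowSums(x)
  lp <- log(p)
  out <- lgamma(n + 1) - rowSums(lgamma(x + 1))
  for (k in 1:3) {
    term <- x[, k] * lp[k]
    term[x[, k] == 0] <- 0  # 0 * log(0) = 0 by convention
    out <- out + term
  }
  unname(out)
}

# All compositions of n into three parts, their log-pmf, and the exact
# tail probability of each under point-probability ordering. Returned as
# a lookup matrix tail[x1 + 1, x2 + 1].
multinomial_tail_table <- function(n, p) {
  x1 <- rep(0:n, times = (n + 1):1)
  x2 <- unlist(lapply(0:n, function(a) 0:(n - a)), use.names = FALSE)
  x3 <- n - x1 - x2
  lp <- trinomial_logpmf(x1, x2, x3, p)
  o <- order(lp)
  lp_s <- lp[o]
  cs <- cumsum(exp(lp_s))
  # outcomes whose log-pmf ties (within tolerance) share the tail value
  grp <- cumsum(c(TRUE, diff(lp_s) > 1e-9))
  tail_s <- stats::ave(cs, grp, FUN = max)
  tail <- numeric(length(lp))
  tail[o] <- pmin(tail_s, 1)
  m <- matrix(NA_real_, n + 1, n + 1)
  m[cbind(x1 + 1, x2 + 1)] <- tail
  m
}

#' Exact multinomial tail probability
#'
#' The exact multinomial test with point-probability ordering:
#' `P = sum of pmf(y)` over all outcomes `y` of the same total whose
#' probability does not exceed that of the observed combination. Equals 1
#' at the modal outcome and is never smaller than the observed pmf.
#'
#' @inheritParams trinomial_pmf
#' @return Exact tail probability (vectorised; totals may differ between
#'   entries but each total must be at most 10,000).
#' @export
exact_multinomial_tail <- function(x1, x2, x3, p) {
  x <- cbind(x1, x2, x3)
  n <- rowSums(x)
  if (any(n > 10000)) stop_param("n too large for exact enumeration")
  out <- numeric(nrow(x))
  for (nn in unique(n)) {
    tab <- multinomial_tail_table(nn, p)
    i <- which(n == nn)
    out[i] <- tab[cbind(x[i, 1] + 1, x[i, 2] + 1)]
  }
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment: sort p ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j` clipped at 1, and restore the
#' original order.
#'
#' @param p_values Numeric vector in `[0, 1]`; `NA`/`NaN` is an error.
#' @return q-values in the original order.
#' @export
bh_qvalues <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_param("p-values must be finite and in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  q <- pmin(rev(cummin(rev(p_values[o] * m / seq_len(m)))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Per-ancestry log-fold enrichment
#'
#' `log2(x_k / (n * p_k))` per ancestry: observed counts over the
#' genomic-average expectation. A zero count gives `-Inf`; for plotting,
#' floor it (e.g. at the value corresponding to half a chromosome,
#' `log2(0.5 / (n p_k))`).
#'
#' @param counts Locus-count data frame (or a single row).
#' @param expected Probability 3-vector.
#' @return Matrix with columns `lf_AFR`, `lf_NAM`, `lf_EUR`.
#' @export
logfold_enrichment <- function(counts, expected) {
  x <- as.matrix(counts[, c("x_AFR", "x_NAM", "x_EUR")])
  e <- outer(counts$n, unname(expected))
  lf <- log2(x / e)
  colnames(lf) <- paste0("lf_", ANCESTRIES)
  lf
}

#' Genome-wide ancestry-enrichment scan
#'
#' Computes population-average proportions from the scanned loci, the
#' per-locus trinomial point probability (`pmf`, the replication score)
#' and the exact multinomial tail probability (`exact_tail`, the
#' calibrated score), BH q-values over the chosen score, log-fold
#' enrichments, and flags loci whose chosen score passes `alpha_p`. Loci
#' with `n = 0` are excluded from the BH denominator and carry `NA`
#' statistics.
#'
#' @param segments Validated segment data frame.
#' @param windows Locus-window data frame.
#' @param alpha_p Significance threshold on the chosen score.
#' @param score `"pmf"` (the point probability itself, used for the
#'   headline scan) or `"exact_tail"` (a calibrated P-value; preferred
#'   for inference). Both columns are always reported.
#' @param chrom_class Scan autosomes (default) or the X.
#' @param expected Optional fixed probability 3-vector; by default the
#'   pooled proportions of the scanned loci.
#' @param x_chrom Name of the X chromosome.
#' @return Data frame of class `enrichment_scan`: locus columns, counts,
#'   `pmf_score`, `tail_p`, `score` (the chosen one), `q_value`,
#'   `lf_AFR`/`lf_NAM`/`lf_EUR`, `significant`, `enriched_ancestry`,
#'   `depleted_ancestry`. The expected proportions, score choice and
#'   threshold are attached as attributes.
#' @export
scan_genome <- function(segments, windows, alpha_p = 1e-9,
                        score = c("pmf", "exact_tail"),
                        chrom_class = c("autosome", "X"), expected = NULL,
                        x_chrom = "chrX") {
  score <- match.arg(score)
  chrom_class <- match.arg(chrom_class)
  cnt <- locus_counts(segments, windows, chrom_class, x_chrom)
  obs <- cnt$n > 0
  if (!any(obs)) stop_param("no locus has observed chromosomes")
  if (sum(!obs))
    message("scan_genome: ", sum(!obs),
            " locus/loci with n = 0 excluded from the FDR denominator")
  p <- if (is.null(expected)) population_average_proportions(cnt[obs, ])
       else check_prob_vector(expected, "expected")
  res <- cnt
  res$pmf_score <- NA_real_
  res$tail_p <- NA_real_
  res$pmf_score[obs] <- trinomial_pmf(cnt$x_AFR[obs], cnt$x_NAM[obs],
                                      cnt$x_EUR[obs], p)
  res$tail_p[obs] <- exact_multinomial_tail(cnt$x_AFR[obs], cnt$x_NAM[obs],
                                            cnt$x_EUR[obs], p)
  res$score <- if (score == "pmf") res$pmf_score else res$tail_p
  res$q_value <- NA_real_
  res$q_value[obs] <- bh_qvalues(res$score[obs])
  lf <- matrix(NA_real_, nrow(res), 3,
               dimnames = list(NULL, paste0("lf_", ANCESTRIES)))
  lf[obs, ] <- logfold_enrichment(cnt[obs, ], p)
  res <- cbind(res, lf)
  res$significant <- !is.na(res$score) & res$score < alpha_p
  res$enriched_ancestry <- NA_character_
  res$depleted_ancestry <- NA_character_
  if (any(res$significant)) {
    sig <- which(res$significant)
    lfs <- lf[sig, , drop = FALSE]
    res$enriched_ancestry[sig] <- ANCESTRIES[apply(lfs, 1, which.max)]
    # ties at -Inf (several absent ancestries): the most depleted is the
    # one with the largest expectation
    res$depleted_ancestry[sig] <- ANCESTRIES[apply(lfs, 1, function(v) {
      i <- which(v == min(v))
      if (length(i) > 1) i <- i[which.max(p[i])]
      i
    })]
  }
  attr(res, "expected") <- p
  attr(res, "score_type") <- score
  attr(res, "alpha_p") <- alpha_p
  class(res) <- c("enrichment_scan", "data.frame")
  res
}

#' Frequencies of three-way ancestry count combinations
#'
#' The heatmap statistic: the population frequency of each observed
#' `(x_AFR, x_NAM)` combination over loci (the third count is determined
#' by the other two). When loci have heterogeneous totals, combinations
#' are binned by proportion on a fixed 21-level grid (0, 0.05, ..., 1)
#' instead of raw counts.
#'
#' @param counts Locus-count data frame (loci with `n = 0` are dropped).
#' @return Data frame `x_AFR`, `x_NAM`, `frequency` (summing to 1), with
#'   attribute `mode` = `"counts"` or `"proportions"`.
#' @export
combination_frequency_grid <- function(counts) {
  cnt <- counts[counts$n > 0, ]
  if (nrow(cnt) == 0) stop_param("no loci with observations")
  if (length(unique(cnt$n)) == 1L) {
    key <- paste(cnt$x_AFR, cnt$x_NAM)
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " "))
    out <- data.frame(x_AFR = as.numeric(parts[, 1]),
                      x_NAM = as.numeric(parts[, 2]),
                      frequency = as.numeric(tab) / nrow(cnt))
    mode <- "counts"
  } else {
    b1 <- round(cnt$x_AFR / cnt$n * 20) / 20
    b2 <- round(cnt$x_NAM / cnt$n * 20) / 20
    key <- paste(b1, b2)
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " "))
    out <- data.frame(x_AFR = as.numeric(parts[, 1]),
                      x_NAM = as.numeric(parts[, 2]),
                      frequency = as.numeric(tab) / nrow(cnt))
    mode <- "proportions"
  }
  out <- out[order(out$x_AFR, out$x_NAM), ]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Merge adjacent significant loci into enriched segments
#'
#' Consecutive significant loci on one chromosome sharing the same
#' enriched ancestry merge into a single segment carrying the smallest
#' tail probability; a change of enriched ancestry, an intervening
#' non-significant locus, or a chromosome break starts a new segment.
#'
#' @param results An `enrichment_scan` data frame.
#' @return Data frame `chrom`, `start`, `end`, `ancestry`, `n_loci`,
#'   `min_p` (minimum of the chosen score over merged loci).
#' @export
merge_significant_segments <- function(results) {
  sig <- results[results$significant, ]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), ancestry = character(),
                      n_loci = integer(), min_p = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(empty)
  idx <- which(results$significant)
  new_run <- c(TRUE, diff(idx) != 1L |
                 sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                 sig$enriched_ancestry[-1] !=
                   sig$enriched_ancestry[-nrow(sig)])
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(sig, run), function(s) {
    data.frame(chrom = s$chrom[1], start = min(s$start), end = max(s$end),
               ancestry = s$enriched_ancestry[1], n_loci = nrow(s),
               min_p = min(s$score), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Annotate segments with overlapping genes
#'
#' Reports genes overlapping each segment by at least one base under
#' half-open coordinates (a gene that merely abuts a segment end does not
#' overlap). Gene names are sorted by gene start.
#'
#' @param segments Data frame with `chrom`, `start`, `end` (e.g. from
#'   [merge_significant_segments()]).
#' @param genes Gene data frame from [read_gene_bed()].
#' @return `segments` with an added `genes` column (comma-separated,
#'   empty string when none).
#' @export
annotate_genes <- function(segments, genes) {
  segments$genes <- character(nrow(segments))
  if (nrow(segments) == 0 || nrow(genes) == 0) return(segments)
  gr_seg <- segments_to_granges(segments$chrom, segments$start,
                                segments$end)
  gr_gen <- segments_to_granges(genes$chrom, genes$start, genes$end)
  ov <- GenomicRanges::findOverlaps(gr_seg, gr_gen)
  if (length(ov)) {
    hits <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    for (q in names(hits)) {
      g <- genes[hits[[q]], ]
      g <- g[order(g$start), ]
      segments$genes[as.integer(q)] <- paste(g$name, collapse = ",")
    }
  }
  segments
}
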