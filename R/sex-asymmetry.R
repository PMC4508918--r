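# Sex-specific admixture asymmetry: the X-versus-autosome admixture
# difference ratio, its bootstrap confidence interval, and bootstrap
# tests between cohorts and against zero.

#' X-versus-autosome admixture difference ratio
#'
#' For one ancestry, `delta = (F_X - F_auto) / F_total`, where `F_X`,
#' `F_auto` and `F_total` are the X-chromosome, autosomal and genome-wide
#' admixture proportions of that ancestry. Because X chromosomes spend
#' two thirds of their history in females, positive values indicate an
#' excess of female-line (maternal) contributions of that ancestry and
#' negative values an excess of male-line (paternal) contributions.
#'
#' @param f_x,f_auto,f_total Proportions in `[0, 1]`; `f_total` must be
#'   positive (the ratio is undefined for an absent ancestry).
#' @return The dimensionless ratio (vectorised).
#' @export
delta_admix <- function(f_x, f_auto, f_total) {
  v <- c(f_x, f_auto, f_total)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop_param("all fractions must be in [0, 1]")
  if (any(f_total == 0))
    stop_param("F_total is 0: the ratio is undefined for an absent ancestry")
  (f_x - f_auto) / f_total
}

# Per-individual arrays for fast pooled/bootstrap computation: for each
# compartment, covered length and length*fraction per ancestry, aligned
# to the individual index (0 where the compartment is absent).
records_arrays <- function(records) {
  ids <- unique(records$individual)
  arr <- list(ids = ids)
  for (comp in c("auto", "X", "total")) {
    rc <- records[records$compartment == comp, ]
    len <- numeric(length(ids))
    w <- matrix(0, length(ids), 3, dimnames = list(NULL, ANCESTRIES))
    m <- match(rc$individual, ids)
    len[m] <- rc$len
    w[m, ] <- as.matrix(rc[, ANCESTRIES]) * rc$len
    arr[[comp]] <- list(len = len, w = w)
  }
  arr
}

pooled_delta <- function(arr, idx, ancestry) {
  lx <- sum(arr$X$len[idx]); la <- sum(arr$auto$len[idx])
  lt <- sum(arr$total$len[idx])
  if (lx == 0 || la == 0 || lt == 0) return(NA_real_)
  f_x <- sum(arr$X$w[idx, ancestry]) / lx
  f_auto <- sum(arr$auto$w[idx, ancestry]) / la
  f_total <- sum(arr$total$w[idx, ancestry]) / lt
  if (f_total == 0) return(NA_real_)
  (f_x - f_auto) / f_total
}

#' Cohort-level admixture difference ratio
#'
#' Pools individuals before taking the ratio: cohort `F_X`, `F_auto` and
#' `F_total` are length-weighted means over individuals, and
#' [delta_admix()] is applied to the pooled values. Pooling is robust
#' when an ancestry is near zero in some individuals, where
#' per-individual ratios are unstable.
#'
#' @param records Long ancestry-fraction data frame from
#'   [fractions_from_tracts()] (or EM fractions arranged the same way).
#' @param ancestry One of `"AFR"`, `"NAM"`, `"EUR"`.
#' @return The cohort ratio.
#' @export
cohort_delta <- function(records, ancestry) {
  ancestry <- match.arg(ancestry, ANCESTRIES)
  arr <- records_arrays(records)
  if (sum(arr$X$len > 0) < 2)
    stop_param("need X-chromosome data for at least two individuals")
  d <- pooled_delta(arr, seq_along(arr$ids), ancestry)
  if (is.na(d))
    stop_param("cohort F_total is 0 for ancestry ", ancestry)
  d
}

# n_boot bootstrap replicates of the pooled cohort delta, resampling
# individuals with replacement. Replicates where the ancestry (or a
# compartment) vanishes are redrawn, capped at 10 * n_boot attempts.
boot_deltas <- function(records, ancestry, n_boot, seed) {
  arr <- records_arrays(records)
  n <- length(arr$ids)
  with_seed(seed, {
    out <- numeric(n_boot)
    redraws <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        d <- pooled_delta(arr, sample.int(n, n, replace = TRUE), ancestry)
        if (!is.na(d)) break
        redraws <- redraws + 1L
        if (redraws > 10L * n_boot)
          stop_param("bootstrap exhausted: ancestry ", ancestry,
                     " absent from too many replicates")
      }
      out[b] <- d
    }
    attr(out, "redraws") <- redraws
    out
  })
}

#' Bootstrap confidence interval for the cohort delta
#'
#' Resamples individuals with replacement, recomputes the pooled cohort
#' ratio per replicate, and reports the percentile interval.
#'
#' @inheritParams cohort_delta
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed; fixed seed gives an identical interval.
#' @return One-row data frame: `ancestry`, `delta` (full-sample ratio),
#'   `ci_low`, `ci_high`, `n_boot`, `n_individuals`, `n_redraws`.
#' @export
bootstrap_ci <- function(records, ancestry, n_boot = 1000, level = 0.95,
                         seed = 1L) {
  ancestry <- match.arg(ancestry, ANCESTRIES)
  n_ind <- length(unique(records$individual))
  if (n_ind < 5) stop_param("need at least 5 individuals")
  point <- cohort_delta(records, ancestry)
  d <- boot_deltas(records, ancestry, n_boot, seed)
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(d, c(a, 1 - a)))
  data.frame(ancestry = ancestry, delta = point, ci_low = ci[1],
             ci_high = ci[2], n_boot = n_boot, n_individuals = n_ind,
             n_redraws = attr(d, "redraws"), stringsAsFactors = FALSE)
}

# Content-derived seed so a population's bootstrap stream does not depend
# on argument order (swapping cohorts leaves the test invariant).
population_seed <- function(seed, records) {
  substream_seed(seed, paste(sort(unique(records$individual)),
                             collapse = ","))
}

#' Bootstrap test comparing two cohorts' deltas
#'
#' Bootstraps each cohort's pooled ratio independently and forms the
#' replicate distribution of the difference. The two-sided P-value is
#' `2 * min(Pr(diff <= 0), Pr(diff >= 0))` with the `(k + 1)/(n_boot + 1)`
#' small-sample correction, so P is never below `2 / (n_boot + 1)`.
#' Each cohort's resampling stream is derived from its own individual
#' ids, so swapping the arguments leaves P unchanged.
#'
#' @param records_a,records_b Ancestry-fraction records of the two
#'   cohorts (>= 5 individuals each).
#' @inheritParams bootstrap_ci
#' @return Two-sided P-value.
#' @export
compare_populations <- function(records_a, records_b, ancestry,
                                n_boot = 1000, seed = 1L) {
  ancestry <- match.arg(ancestry, ANCESTRIES)
  if (length(unique(records_a$individual)) < 5 ||
      length(unique(records_b$individual)) < 5)
    stop_param("need at least 5 individuals per cohort")
  da <- boot_deltas(records_a, ancestry, n_boot,
                    population_seed(seed, records_a))
  db <- boot_deltas(records_b, ancestry, n_boot,
                    population_seed(seed, records_b))
  diff <- da - db
  min(1, 2 * min(sum(diff <= 0) + 1, sum(diff >= 0) + 1) / (n_boot + 1))
}

#' Bootstrap test of a cohort delta against zero
#'
#' Same correction and floor as [compare_populations()], with the second
#' cohort replaced by the null value 0.
#'
#' @inheritParams bootstrap_ci
#' @return Two-sided P-value.
#' @export
test_nonzero <- function(records, ancestry, n_boot = 1000, seed = 1L) {
  ancestry <- match.arg(ancestry, ANCESTRIES)
  if (length(unique(records$individual)) < 5)
    stop_param("need at least 5 individuals")
  d <- boot_deltas(records, ancestry, n_boot, seed)
  min(1, 2 * min(sum(d <= 0) + 1, sum(d >= 0) + 1) / (n_boot + 1))
}
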