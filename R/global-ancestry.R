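# Global ancestry: allele-sharing distances and their PCA, supervised EM
# ancestry proportions against fixed reference allele frequencies, and
# tract-length ancestry fractions split by genomic compartment.

#' Pairwise allele-sharing distance matrix
#'
#' The distance between two genomes is the fraction of allelic differences
#' between their SNP calls, on the dosage scale: each SNP contributes
#' `|g_i - g_j| / 2`, so identical calls contribute 0, opposite homozygotes
#' 1 and het-versus-hom 1/2. Only SNPs non-missing in both samples enter a
#' pair's mean. The result is symmetric with zero diagonal; it is not
#' guaranteed to satisfy the triangle inequality.
#'
#' @param gm A `genotype_matrix` (see [read_genotypes_vcf()]).
#' @return List of class `asd_matrix` with `dist` (symmetric matrix in
#'   `[0, 1]`) and `n_shared` (SNPs compared per pair).
#' @export
allele_sharing_distance <- function(gm) {
  x <- gm$dosage
  n <- ncol(x)
  if (n < 2) stop_param("need at least two samples")
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  ns <- matrix(nrow(x), n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      if (!any(ok))
        stop_param("no shared non-missing SNPs for pair (",
                   gm$samples[i], ", ", gm$samples[j], ")")
      d[i, j] <- d[j, i] <- mean(abs(x[ok, i] - x[ok, j])) / 2
      ns[i, j] <- ns[j, i] <- sum(ok)
    }
  }
  structure(list(dist = d, n_shared = ns), class = "asd_matrix")
}

#' Principal components of a distance matrix
#'
#' Mirrors a scaled PCA of the pairwise distance matrix: rows are
#' observations, columns are centered and scaled to unit variance
#' (columns with zero variance are centered only), then decomposed by
#' SVD. Explained-variance fractions are non-increasing and sum to at
#' most 1.
#'
#' @param distances An `asd_matrix` or a plain symmetric matrix.
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components), `explained`
#'   (variance fractions for all components) and `sdev`.
#' @export
pca_project <- function(distances, n_components = 2) {
  m <- if (inherits(distances, "asd_matrix")) distances$dist
       else as.matrix(distances)
  if (n_components > nrow(m))
    stop_param("n_components exceeds the number of samples")
  ctr <- scale(m, center = TRUE, scale = FALSE)
  sds <- apply(ctr, 2, stats::sd)
  sds[sds == 0] <- 1
  z <- sweep(ctr, 2, sds, "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- rownames(m)
  list(scores = scores, explained = expl, sdev = pc$sdev)
}

#' Supervised ancestry proportions by EM
#'
#' Estimates each individual's three-way ancestry proportions by
#' maximising the binomial likelihood of its genotypes given fixed
#' reference allele frequencies: the alternate-allele probability at a
#' SNP is the ancestry-weighted mixture `sum_k q_k f_k`. The EM update
#' computes the expected ancestry of each allele copy and renormalises;
#' the log-likelihood is non-decreasing. Initialisation is the uniform
#' simplex point, so runs are deterministic. Hemizygous entries (ploidy
#' 1) contribute one allele copy.
#'
#' @param gm A `genotype_matrix`.
#' @param freqs Allele-frequency table (`chrom`, `pos`, `freq_AFR`,
#'   `freq_NAM`, `freq_EUR`); matched to the genotypes by chrom+pos, and
#'   frequencies clipped to `[1e-6, 1 - 1e-6]`.
#' @param tol Stop when the log-likelihood improves by less than this.
#' @param max_iter Iteration cap; hitting it raises a warning, not an
#'   error.
#' @return List of class `supervised_em` with `Q` (individuals x
#'   AFR/NAM/EUR), `loglik` (final per-individual log-likelihood),
#'   `trace` (per-individual log-likelihood traces), `n_iter`,
#'   `converged`.
#' @export
supervised_admixture_em <- function(gm, freqs, tol = 1e-8, max_iter = 5000) {
  key_g <- paste(gm$snps$chrom, gm$snps$pos)
  key_f <- paste(freqs$chrom, freqs$pos)
  idx <- match(key_g, key_f)
  use <- which(!is.na(idx))
  if (length(use) == 0)
    stop_param("no SNP overlap between genotypes and frequency table")
  fmat <- as.matrix(freqs[idx[use],
                          c("freq_AFR", "freq_NAM", "freq_EUR")])
  fmat <- pmin(pmax(fmat, 1e-6), 1 - 1e-6)
  n_ind <- length(gm$samples)
  q_all <- matrix(NA_real_, n_ind, 3,
                  dimnames = list(gm$samples, ANCESTRIES))
  traces <- vector("list", n_ind)
  n_iter <- integer(n_ind)
  converged <- logical(n_ind)
  ll_final <- numeric(n_ind)
  for (i in seq_len(n_ind)) {
    g <- gm$dosage[use, i]
    cpl <- gm$ploidy[use, i]
    ok <- !is.na(g)
    gi <- g[ok]; ci <- cpl[ok]; f <- fmat[ok, , drop = FALSE]
    f1 <- 1 - f
    q <- rep(1 / 3, 3)
    ll_old <- -Inf
    tr <- numeric(0)
    it <- 0L
    repeat {
      it <- it + 1L
      mu <- as.vector(f %*% q)
      ll <- sum(gi * log(mu) + (ci - gi) * log1p(-mu))
      tr <- c(tr, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
        converged[i] <- TRUE
        break
      }
      if (it >= max_iter) break
      ll_old <- ll
      # E-step: expected ancestry-of-allele counts (q_k f_k / mu per alt
      # copy, q_k (1-f_k) / (1-mu) per ref copy), then renormalise
      num <- q * (crossprod(f, gi / mu) +
                    crossprod(f1, (ci - gi) / (1 - mu)))
      q <- as.vector(num / sum(num))
    }
    if (!converged[i])
      warning("EM did not converge for ", gm$samples[i], " after ",
              max_iter, " iterations")
    q_all[i, ] <- q
    traces[[i]] <- tr
    n_iter[i] <- it
    ll_final[i] <- tr[length(tr)]
  }
  structure(list(Q = q_all, loglik = ll_final, trace = traces,
                 n_iter = n_iter, converged = converged,
                 n_snps = length(use)),
            class = "supervised_em")
}

#' Ancestry fractions from tract lengths
#'
#' Per-ancestry fraction = covered length with that ancestry / total
#' covered length, computed per individual for three compartments:
#' autosomes (`auto`), the X chromosome (`X`) and their union (`total`).
#' Missing coverage (gaps between segments) is excluded from
#' denominators. A compartment with zero covered length is simply absent
#' from the output.
#'
#' @param segments Validated segment data frame (see [read_segments()]).
#' @param chrom_lengths Named chromosome lengths (used only to decide
#'   which chromosomes exist; fractions use covered lengths).
#' @param sexes Optional named `"M"`/`"F"` vector by individual id.
#' @param x_chrom Name of the X chromosome.
#' @return Long data frame with one row per individual x compartment:
#'   `individual`, `sex`, `compartment`, `len` (covered bp), and
#'   fraction columns `AFR`, `NAM`, `EUR` (each row sums to 1).
#' @export
fractions_from_tracts <- function(segments, chrom_lengths = NULL,
                                  sexes = NULL, x_chrom = "chrX") {
  seg <- segments
  seg$len <- seg$end - seg$start
  seg$isx <- seg$chrom == x_chrom
  out <- list()
  for (id in unique(seg$individual)) {
    si <- seg[seg$individual == id, ]
    sx <- if (!is.null(sexes) && id %in% names(sexes)) sexes[[id]]
          else NA_character_
    for (comp in c("auto", "X", "total")) {
      sc <- switch(comp, auto = si[!si$isx, ], X = si[si$isx, ], total = si)
      tot <- sum(sc$len)
      if (tot == 0) next
      fr <- vapply(ANCESTRIES,
                   function(a) sum(sc$len[sc$ancestry == a]) / tot,
                   numeric(1))
      out[[length(out) + 1L]] <-
        data.frame(individual = id, sex = sx, compartment = comp,
                   len = tot, AFR = fr[["AFR"]], NAM = fr[["NAM"]],
                   EUR = fr[["EUR"]], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
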