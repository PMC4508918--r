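#' @keywords internal
"_PACKAGE"

#' Canonical three-way ancestry labels
#'
#' The internal ancestry alphabet, in fixed order: African (AFR),
#' Native American (NAM) and European (EUR). All segment, count and
#' proportion vectors in the package follow this order. Reference-panel
#' labels (e.g. YRI/CHB/CEU) are translated to this alphabet at the I/O
#' boundary via a label map.
#'
#' @format Character vector of length 3.
#' @export
ANCESTRIES <- c("AFR", "NAM", "EUR")

# Default label map for the common reference-panel surrogates.
DEFAULT_LABEL_MAP <- c(YRI = "AFR", CHB = "NAM", CEU = "EUR",
                       AFR = "AFR", NAM = "NAM", EUR = "EUR")

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All stochastic stages draw from named, order-stable substreams derived
#' from one master seed, so that adding draws to one stage never perturbs
#' another. The derivation is a small string hash folded into the master
#' seed, kept below 2^31 so it is a valid R integer seed.
#'
#' @param seed Master integer seed.
#' @param name Stream name (character scalar).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(as.character(name))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 1) %% 2147483647)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Convert between 0-based half-open and 1-based closed coordinates
#'
#' All coordinates inside the package are 0-based half-open (BED
#' convention). VCF POS and IRanges are 1-based; these converters are the
#' single place where the shift happens.
#'
#' @param start0 0-based start (inclusive).
#' @param pos1 1-based position.
#' @return The converted coordinate.
#' @export
bed0_to_pos1 <- function(start0) start0 + 1L

#' @rdname bed0_to_pos1
#' @export
pos1_to_bed0 <- function(pos1) pos1 - 1L

# segments (0-based half-open) -> GRanges (1-based closed)
segments_to_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

# Natural ordering of chromosome names: chr1 < chr2 < ... < chr22 < chrX.
chrom_order <- function(chroms) {
  u <- unique(chroms)
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  key <- ifelse(is.na(num), 1e6 + as.numeric(factor(u)), num)
  u[order(key)]
}

stop_param <- function(...) stop(..., call. = FALSE)

check_prob_vector <- function(p, name, tol = 1e-12) {
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p)) || any(p < 0))
    stop_param(name, " must be a non-negative numeric 3-vector")
  if (abs(sum(p) - 1) > tol)
    stop_param(name, " must sum to 1 (got ", format(sum(p), digits = 15), ")")
  p <- as.numeric(p)
  names(p) <- ANCESTRIES
  p
}
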