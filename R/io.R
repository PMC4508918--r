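# Readers and writers for every external format the pipeline touches.
# All on-disk coordinates are 0-based half-open (BED convention) except
# VCF POS, which is converted at this boundary.

PAINT_COLORS <- c(AFR = "228,26,28", NAM = "77,175,74", EUR = "55,126,184")

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stop_param(what, " file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read per-haplotype ancestry segments
#'
#' Segment files are 6-column TSVs with a header:
#' `individual`, `haplotype` (0/1), `chrom`, `start`, `end` (0-based
#' half-open) and `ancestry`. Labels outside the canonical AFR/NAM/EUR
#' alphabet are translated through `label_map` (by default the
#' YRI/CHB/CEU reference-panel surrogates). Coverage gaps are permitted —
#' downstream per-locus denominators account for them — but overlapping
#' segments on one haplotype are a format error.
#'
#' @param path File path.
#' @param label_map Named character vector mapping input ancestry labels
#'   to `AFR`/`NAM`/`EUR`.
#' @return Validated, sorted segment data frame.
#' @export
read_segments <- function(path, label_map = DEFAULT_LABEL_MAP) {
  df <- read_tsv_checked(path, "segment")
  need <- c("individual", "haplotype", "chrom", "start", "end", "ancestry")
  if (!all(need %in% names(df)))
    stop_param("segment file must have columns ",
               paste(need, collapse = ", "))
  df <- df[, need]
  df$haplotype <- as.integer(df$haplotype)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (nrow(df) == 0) return(df)
  if (any(is.na(df$haplotype)) || !all(df$haplotype %in% c(0L, 1L)))
    stop_param("haplotype must be 0 or 1")
  df$line <- seq_len(nrow(df)) + 1L  # header is line 1
  mapped <- unname(label_map[df$ancestry])
  bad <- which(is.na(mapped) | !(mapped %in% ANCESTRIES))
  if (length(bad))
    stop_param("unknown ancestry label '", df$ancestry[bad[1]],
               "' at line ", df$line[bad[1]])
  df$ancestry <- mapped
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop_param("segment with start >= end at line ", df$line[bad[1]])
  df <- df[order(df$individual, df$haplotype, df$chrom, df$start), ]
  grp <- paste(df$individual, df$haplotype, df$chrom)
  same <- grp[-1] == grp[-nrow(df)]
  ovl <- which(same & df$start[-1] < df$end[-nrow(df)])
  if (length(ovl))
    stop_param("overlapping segments on one haplotype at line ",
               df$line[ovl[1] + 1L])
  df$line <- NULL
  rownames(df) <- NULL
  df
}

#' @rdname read_segments
#' @param segments Segment data frame.
#' @export
write_segments <- function(segments, path) {
  df <- segments[, c("individual", "haplotype", "chrom", "start", "end",
                     "ancestry")]
  df$start <- fmt_coord(df$start)
  df$end <- fmt_coord(df$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_bed_lines <- function(path, what) {
  if (!file.exists(path)) stop_param(what, " file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(NULL)
  utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
}

#' Read recombination-derived locus windows (BED)
#'
#' BED-like file with at least `chrom`, `start`, `end`; an optional fourth
#' column supplies locus ids (otherwise ids are generated). Windows must
#' not overlap within a chromosome.
#'
#' @param path File path.
#' @return Sorted window data frame (`chrom`, `start`, `end`, `locus_id`).
#' @export
read_locus_windows <- function(path) {
  raw <- read_bed_lines(path, "locus window")
  if (is.null(raw))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), locus_id = character(),
                      stringsAsFactors = FALSE))
  df <- data.frame(chrom = raw[[1]], start = as.numeric(raw[[2]]),
                   end = as.numeric(raw[[3]]), stringsAsFactors = FALSE)
  df$locus_id <- if (ncol(raw) >= 4) as.character(raw[[4]])
                 else sprintf("L%06d", seq_len(nrow(df)))
  if (any(df$start >= df$end)) stop_param("window with start >= end")
  df <- df[order(match(df$chrom, chrom_order(df$chrom)), df$start), ]
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  if (nrow(df) > 1 && any(same & df$start[-1] < df$end[-nrow(df)]))
    stop_param("overlapping locus windows on one chromosome")
  rownames(df) <- NULL
  df
}

#' @rdname read_locus_windows
#' @param windows Window data frame.
#' @export
write_locus_windows <- function(windows, path) {
  df <- data.frame(windows$chrom, fmt_coord(windows$start),
                   fmt_coord(windows$end), windows$locus_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ancestral allele frequencies
#'
#' TSV with header columns `chrom`, `pos` (0-based), `ref`, `alt`,
#' `freq_AFR`, `freq_NAM`, `freq_EUR`. Frequencies outside `[0, 1]` are a
#' format error.
#'
#' @param path File path.
#' @return Allele-frequency data frame.
#' @export
read_allele_freqs <- function(path) {
  df <- read_tsv_checked(path, "allele frequency")
  need <- c("chrom", "pos", "ref", "alt", "freq_AFR", "freq_NAM", "freq_EUR")
  if (!all(need %in% names(df)))
    stop_param("allele frequency file must have columns ",
               paste(need, collapse = ", "))
  df <- df[, need]
  fr <- as.matrix(df[, c("freq_AFR", "freq_NAM", "freq_EUR")])
  if (nrow(df) && (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)))
    stop_param("allele frequency outside [0, 1]")
  df[order(match(df$chrom, chrom_order(df$chrom)), df$pos), , drop = FALSE]
}

#' @rdname read_allele_freqs
#' @param freqs Allele-frequency data frame.
#' @export
write_allele_freqs <- function(freqs, path) {
  df <- freqs
  df$pos <- fmt_coord(df$pos)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations (BED4)
#'
#' @param path File path to a BED4 file (`chrom`, `start`, `end`, `name`).
#' @return Sorted gene data frame.
#' @export
read_gene_bed <- function(path) {
  raw <- read_bed_lines(path, "gene")
  if (is.null(raw))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  df <- data.frame(chrom = raw[[1]], start = as.numeric(raw[[2]]),
                   end = as.numeric(raw[[3]]), name = as.character(raw[[4]]),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop_param("gene with start >= end")
  df <- df[order(match(df$chrom, chrom_order(df$chrom)), df$start), ]
  rownames(df) <- NULL
  df
}

#' @rdname read_gene_bed
#' @param genes Gene data frame.
#' @export
write_gene_bed <- function(genes, path) {
  df <- data.frame(genes$chrom, fmt_coord(genes$start),
                   fmt_coord(genes$end), genes$name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a chromosome painting (BED9) for one individual
#'
#' One BED9 line per ancestry segment, with a fixed itemRgb color per
#' ancestry and the two haplotypes written on opposite strands (`+` for
#' haplotype 0, `-` for haplotype 1) so genome browsers can show them as
#' two tracks.
#'
#' @param segments Segment data frame for a single individual.
#' @param path Output path.
#' @param name Track name; defaults to the individual id.
#' @export
write_painting_bed <- function(segments, path, name = NULL) {
  ind <- unique(segments$individual)
  if (length(ind) > 1)
    stop_param("painting is per individual; got ", length(ind))
  if (is.null(name))
    name <- if (length(ind)) paste0("ancestry_", ind) else "ancestry"
  hdr <- sprintf('track name="%s" itemRgb="On"', name)
  if (nrow(segments) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  df <- data.frame(segments$chrom, fmt_coord(segments$start),
                   fmt_coord(segments$end), segments$ancestry, 0L,
                   ifelse(segments$haplotype == 0, "+", "-"),
                   fmt_coord(segments$start), fmt_coord(segments$end),
                   PAINT_COLORS[segments$ancestry])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_painting_bed
#' @export
read_painting_bed <- function(path) {
  first <- readLines(path, n = 1)
  ind <- sub('^track name="(?:ancestry_)?([^"]*)".*$', "\\1", first,
             perl = TRUE)
  raw <- read_bed_lines(path, "painting")
  if (is.null(raw))
    return(data.frame(individual = character(), haplotype = integer(),
                      chrom = character(), start = numeric(),
                      end = numeric(), ancestry = character(),
                      stringsAsFactors = FALSE))
  data.frame(individual = ind,
             haplotype = ifelse(raw[[6]] == "+", 0L, 1L),
             chrom = raw[[1]], start = as.numeric(raw[[2]]),
             end = as.numeric(raw[[3]]),
             ancestry = as.character(raw[[4]]), stringsAsFactors = FALSE)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Parses GT into a dosage matrix (SNP x sample). Multiallelic records are
#' skipped with a message; missing calls become `NA`; haploid calls (male
#' X) yield dosage in `{0, 1}` with ploidy recorded as 1. POS is converted
#' to the package's 0-based convention.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param region Optional `chrom` name; keep only records on it.
#' @return A `genotype_matrix` object (see [sample_genotypes()]).
#' @export
read_genotypes_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop_param("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0 || !("FORMAT" %in% colnames(v@gt)) ||
      !any(grepl("GT", v@gt[, "FORMAT"])))
    stop_param("VCF has no GT field")
  keep <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "." &
    !is.na(fix[, "ALT"])
  if (!is.null(region)) keep <- keep & fix[, "CHROM"] == region
  n_multi <- sum(grepl(",", fix[, "ALT"]))
  if (n_multi > 0)
    message("read_genotypes_vcf: skipped ", n_multi,
            " multiallelic record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  alleles <- function(s) strsplit(s, "[/|]")
  parse1 <- function(col) {
    al <- alleles(col)
    dos <- vapply(al, function(a) {
      if (length(a) == 0 || any(is.na(a)) || any(a == "." | a == ""))
        return(NA_integer_)
      sum(as.integer(a))
    }, integer(1))
    pl <- vapply(al, function(a) max(length(a), 1L), integer(1))
    pl[is.na(dos)] <- 2L  # ploidy of a fully missing call is unknowable

    list(dos = dos, pl = pl)
  }
  parsed <- apply(gt, 2, parse1, simplify = FALSE)
  dosage <- vapply(parsed, `[[`, integer(nrow(gt)), "dos")
  ploidy <- vapply(parsed, `[[`, integer(nrow(gt)), "pl")
  dim(dosage) <- dim(gt); dim(ploidy) <- dim(gt)
  colnames(dosage) <- colnames(ploidy) <- colnames(gt)
  structure(list(samples = colnames(gt),
                 snps = data.frame(chrom = unname(fix[keep, "CHROM"]),
                                   pos = as.numeric(fix[keep, "POS"]) - 1,
                                   ref = unname(fix[keep, "REF"]),
                                   alt = unname(fix[keep, "ALT"]),
                                   stringsAsFactors = FALSE),
                 dosage = dosage, ploidy = ploidy),
            class = "genotype_matrix")
}

#' Write a genotype matrix as VCF
#'
#' Diploid dosages become unphased GT (`0/0`, `0/1`, `1/1`), missing
#' entries `./.`, and hemizygous entries (ploidy 1) haploid calls
#' `0` / `1`.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(gm, path) {
  n_snp <- nrow(gm$snps)
  gt <- matrix("./.", n_snp, length(gm$samples))
  d <- gm$dosage; p <- gm$ploidy
  gt[!is.na(d) & p == 2 & d == 0] <- "0/0"
  gt[!is.na(d) & p == 2 & d == 1] <- "0/1"
  gt[!is.na(d) & p == 2 & d == 2] <- "1/1"
  gt[!is.na(d) & p == 1] <- as.character(d[!is.na(d) & p == 1])
  gt[is.na(d) & p == 1] <- "."
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  body <- cbind(gm$snps$chrom, fmt_coord(bed0_to_pos1(gm$snps$pos)),
                paste0(gm$snps$chrom, "_", fmt_coord(gm$snps$pos)),
                gm$snps$ref, gm$snps$alt, ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
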