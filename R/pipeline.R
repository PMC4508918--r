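# Orchestration: one configurable run over the stages, with a manifest,
# fixed seeds and flat-file outputs (TSV/BED/VCF only; plotting is never
# load-bearing).

#' Pipeline configuration
#'
#' Paths to the external inputs, stage toggles and the analysis
#' parameters with their standard defaults: significance threshold
#' `alpha_p = 1e-9` and `n_boot = 1000` bootstrap replicates.
#'
#' @param segments Path to the segment TSV (required unless `sim_config`
#'   is given).
#' @param vcf,freqs Optional paths to a genotype VCF and an
#'   allele-frequency TSV; both are needed for the supervised-EM and
#'   distance/PCA stages.
#' @param windows Path to a locus-window BED; when absent, windows are
#'   tiled over the segment extents with `window_size`.
#' @param genes Optional gene BED for annotating enriched segments.
#' @param sim_config Optional [cohort_sim_config()]; when given, the
#'   cohort is simulated into `out_dir` and its files are used as inputs.
#' @param out_dir Output directory.
#' @param alpha_p,n_boot,score,level Analysis parameters (see
#'   [scan_genome()] and [bootstrap_ci()]).
#' @param window_size Window width used when tiling windows.
#' @param seed Master seed for the stochastic stages.
#' @param stages Character vector of stages to run, among
#'   `"global"`, `"sexbias"`, `"scan"`, `"report"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(segments = NULL, vcf = NULL, freqs = NULL,
                            windows = NULL, genes = NULL,
                            sim_config = NULL, out_dir = "admixscan_out",
                            alpha_p = 1e-9, n_boot = 1000, score = "pmf",
                            level = 0.95, window_size = 1e6, seed = 1L,
                            stages = c("global", "sexbias", "scan",
                                       "report")) {
  cfg <- list(segments = segments, vcf = vcf, freqs = freqs,
              windows = windows, genes = genes, sim_config = sim_config,
              out_dir = out_dir, alpha_p = alpha_p, n_boot = n_boot,
              score = score, level = level, window_size = window_size,
              seed = as.integer(seed), stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: optional cohort simulation, input reading, global
#' ancestry (tract fractions, and supervised EM plus allele-sharing
#' distances/PCA when genotypes are available), sex-asymmetry ratios with
#' bootstrap confidence intervals, the enrichment scan, and the report
#' tables. Every run writes a JSON manifest (`manifest.json`) recording
#' parameters, seed, input checksums and outputs — also on failure, with
#' the failing stage recorded. A fixed seed makes every output file
#' byte-identical across reruns.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "admixscan",
    version = as.character(utils::packageVersion("admixscan")),
    seed = config$seed,
    parameters = list(alpha_p = config$alpha_p, n_boot = config$n_boot,
                      score = config$score, level = config$level,
                      window_size = config$window_size),
    status = "running", stage = NA_character_, inputs = list(),
    outputs = character(0))
  write_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  on.exit(write_manifest())
  fail <- function(stage, e) {
    manifest$status <<- "failed"
    manifest$stage <<- stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  add_output <- function(path) {
    manifest$outputs <<- c(manifest$outputs, basename(path))
    path
  }
  results <- list()

  # -- configuration / simulation --------------------------------------
  manifest$stage <- "configure"
  tryCatch({
    if (!is.null(config$sim_config)) {
      sim_dir <- file.path(config$out_dir, "sim")
      sim <- simulate_pedigree_cohort(config$sim_config, out_dir = sim_dir)
      config$segments <- file.path(sim_dir, "segments.tsv")
      config$vcf <- file.path(sim_dir, "genotypes.vcf")
      config$freqs <- file.path(sim_dir, "allele_freqs.tsv")
      results$sim <- sim
    }
    need_geno <- any(c("global") %in% config$stages)
    paths <- c(segments = config$segments, vcf = config$vcf,
               freqs = config$freqs, windows = config$windows,
               genes = config$genes)
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (is.null(config$segments))
      stop("a segment file (or sim_config) is required")
    if (length(missing))
      stop("missing input file(s): ",
           paste(names(missing), unname(missing), sep = "=",
                 collapse = ", "))
    manifest$inputs <- as.list(tools::md5sum(unname(paths)))
  }, error = function(e) fail("configure", e))

  manifest$stage <- "read"
  tryCatch({
    results$segments <- read_segments(config$segments)
    sexes <- NULL
    if (!is.null(results$sim)) sexes <- results$sim$sexes
    results$sexes <- sexes
    if (!is.null(config$vcf)) {
      results$genotypes <- read_genotypes_vcf(config$vcf)
      results$freq_table <- read_allele_freqs(config$freqs)
    }
    results$windows <- if (!is.null(config$windows))
      read_locus_windows(config$windows)
    else {
      ext <- stats::aggregate(end ~ chrom, data = results$segments, max)
      lens <- stats::setNames(ext$end, ext$chrom)
      make_locus_windows(lens, config$window_size)
    }
    if (!is.null(config$genes)) results$genes <- read_gene_bed(config$genes)
  }, error = function(e) fail("read", e))

  if ("global" %in% config$stages) {
    manifest$stage <- "global"
    tryCatch({
      lens <- NULL
      results$records <- fractions_from_tracts(results$segments,
                                               sexes = results$sexes)
      utils::write.table(results$records,
                         add_output(file.path(config$out_dir,
                                              "global_ancestry.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(results$genotypes)) {
        results$em <- supervised_admixture_em(results$genotypes,
                                              results$freq_table)
        em_df <- data.frame(individual = rownames(results$em$Q),
                            results$em$Q, source = "supervised_em",
                            row.names = NULL)
        utils::write.table(em_df,
                           add_output(file.path(config$out_dir,
                                                "em_ancestry.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        results$asd <- allele_sharing_distance(results$genotypes)
        utils::write.table(results$asd$dist,
                           add_output(file.path(config$out_dir,
                                                "asd_matrix.tsv")),
                           sep = "\t", quote = FALSE)
        results$pca <- pca_project(results$asd,
                                   min(5, nrow(results$asd$dist)))
        pca_df <- data.frame(individual = rownames(results$pca$scores),
                             results$pca$scores, row.names = NULL)
        utils::write.table(pca_df,
                           add_output(file.path(config$out_dir,
                                                "pca_coords.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }, error = function(e) fail("global", e))
  }

  if ("sexbias" %in% config$stages) {
    manifest$stage <- "sexbias"
    tryCatch({
      asym <- do.call(rbind, lapply(ANCESTRIES, function(a)
        bootstrap_ci(results$records, a, n_boot = config$n_boot,
                     level = config$level,
                     seed = substream_seed(config$seed, paste0("ci_", a)))))
      results$asymmetry <- asym
      utils::write.table(asym,
                         add_output(file.path(config$out_dir,
                                              "sex_asymmetry.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }, error = function(e) fail("sexbias", e))
  }

  if ("scan" %in% config$stages) {
    manifest$stage <- "scan"
    tryCatch({
      results$scan <- scan_genome(results$segments, results$windows,
                                  alpha_p = config$alpha_p,
                                  score = config$score)
      utils::write.table(as.data.frame(results$scan),
                         add_output(file.path(config$out_dir,
                                              "enrichment_scan.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      merged <- merge_significant_segments(results$scan)
      if (!is.null(results$genes))
        merged <- annotate_genes(merged, results$genes)
      results$merged <- merged
      utils::write.table(merged,
                         add_output(file.path(config$out_dir,
                                              "enriched_segments.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      grid <- combination_frequency_grid(results$scan)
      utils::write.table(grid,
                         add_output(file.path(config$out_dir,
                                              "combination_grid.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }, error = function(e) fail("scan", e))
  }

  if ("report" %in% config$stages) {
    manifest$stage <- "report"
    tryCatch({
      if (!is.null(results$scan)) {
        mh <- make_manhattan_table(results$scan)
        utils::write.table(mh,
                           add_output(file.path(config$out_dir,
                                                "manhattan.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      summ <- make_summary(results$records, results$asymmetry,
                           results$scan)
      writeLines(summ,
                 add_output(file.path(config$out_dir, "summary.txt")))
      results$summary <- summ
      ind1 <- unique(results$segments$individual)[1]
      write_painting_bed(
        results$segments[results$segments$individual == ind1, ],
        add_output(file.path(config$out_dir,
                             paste0("painting_", ind1, ".bed"))))
    }, error = function(e) fail("report", e))
  }

  manifest$status <- "ok"
  manifest$stage <- "done"
  results$manifest <- manifest
  invisible(results)
}

#' Manhattan-ready table from a scan
#'
#' One row per scored locus, ordered by genome coordinate, with the
#' midpoint and `-log10` of the chosen score.
#'
#' @param results An `enrichment_scan` data frame.
#' @return Data frame `chrom`, `midpoint`, `neg_log10_score`.
#' @export
make_manhattan_table <- function(results) {
  r <- results[!is.na(results$score), ]
  out <- data.frame(chrom = r$chrom,
                    midpoint = floor((r$start + r$end) / 2),
                    neg_log10_score = -log10(r$score))
  out[order(match(out$chrom, chrom_order(out$chrom)), out$midpoint), ,
      drop = FALSE]
}

#' Human-readable run summary
#'
#' Per-ancestry mean and range of individual genome-wide fractions, the
#' asymmetry table and the significant-locus counts.
#'
#' @param records Ancestry-fraction records.
#' @param asymmetry Optional table from the sex-asymmetry stage.
#' @param scan Optional `enrichment_scan`.
#' @return Character vector of report lines.
#' @export
make_summary <- function(records, asymmetry = NULL, scan = NULL) {
  tot <- records[records$compartment == "total", ]
  lines <- c("admixscan run summary", "",
             sprintf("Individuals: %d", nrow(tot)),
             "Genome-wide ancestry fractions:")
  for (a in ANCESTRIES) {
    v <- tot[[a]]
    lines <- c(lines,
               sprintf("  %s: average = %.1f%%, range = %.1f%%-%.1f%%",
                       a, 100 * mean(v), 100 * min(v), 100 * max(v)))
  }
  if (!is.null(asymmetry)) {
    lines <- c(lines, "", "X-vs-autosome admixture difference ratios:")
    for (i in seq_len(nrow(asymmetry)))
      lines <- c(lines,
                 sprintf("  %s: delta = %+.3f [%+.3f, %+.3f] (n_boot = %d)",
                         asymmetry$ancestry[i], asymmetry$delta[i],
                         asymmetry$ci_low[i], asymmetry$ci_high[i],
                         asymmetry$n_boot[i]))
  }
  if (!is.null(scan)) {
    lines <- c(lines, "",
               sprintf("Enrichment scan: %d loci scored, %d significant (%s < %g)",
                       sum(!is.na(scan$score)), sum(scan$significant),
                       attr(scan, "score_type"), attr(scan, "alpha_p")))
  }
  lines
}
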