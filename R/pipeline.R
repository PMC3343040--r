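#' Build a pipeline configuration
#'
#' The `"test"` preset is the default study-condition configuration used
#' throughout the test suite: 2 chromosomes x 10 Mb, 100 promoters, 3
#' comparative hybridizations, 20 spiked DMRs at a log2 effect of 1.0 (five
#' times the 0.2 channel noise sd), and a 1,000-gene expression matrix with 50
#' planted fold changes.  The `"study"` preset reproduces the full-scale array
#' design constants (15,287 promoters tiled into roughly 713,670 probes)
#' through the same code paths.
#'
#' @param preset `"test"` or `"study"`.
#' @param seed RNG seed driving every stochastic stage.
#' @param n_spiked_dmrs number of planted DMRs.
#' @param ... overrides for any configuration entry (see the returned list).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("test", "study"), seed = 1L,
                            n_spiked_dmrs = 20L, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "test") {
    list(chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
         n_promoters = 100L)
  } else {
    # 21 chromosomes sized so 15,287 promoter windows fit
    list(chrom_lengths = setNames(rep(5.2e6, 21),
                                  c(paste0("chr", 1:20), "chrX")),
         n_promoters = 15287L)
  }
  cfg <- c(base, list(
    preset = preset, seed = seed,
    cpg_density_range = c(0.5, 3), margin_bp = 2000L,
    spacing = 100L, length_range = c(50L, 75L),
    n_hybridizations = 3L, noise_sd = 0.2, effect_m = 1.0,
    spike_width_bp = 800L, n_spiked_dmrs = as.integer(n_spiked_dmrs),
    n_bins = 5L, span = 0.4,
    window_bp = 600, min_probes = 3L, smooth_scope = "pair",
    probe_p = 1e-5, region_p = 1e-7, gap_bp = 600,
    intensity_floor = 9.5, density_floor = 1,
    n_genes = 1000L, n_de_genes = 50L,
    ratio_threshold = 1.20, diff_threshold = 10, p_threshold = 0.05,
    ecr_window_range = c(2e6, 5e6), ecr_step = 5e5, ecr_min_genes = 4L,
    ecr_alpha = 0.05))
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> MA conversion -> GC-binned loess -> A-quantile
#' normalization -> per-pair smoothing and probe statistics -> DMR calling ->
#' expression simulation and DE filter -> integration (gene overlap, cluster
#' scan, DMR-cluster overlap, chromosome plot table).  When `out_dir` is
#' given, every stage output and a resolved-config snapshot are persisted
#' there as plain-text files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if absent).
#' @return invisible list with all stage outputs: genome, design, truth, raw,
#'   ma, profiles, dmrs, expression, de, overlap, ecrs, ecr_overlap,
#'   plot_table, config.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gcfg <- genome_config(chrom_lengths = config$chrom_lengths,
                        n_promoters = config$n_promoters,
                        cpg_density_range = config$cpg_density_range,
                        margin_bp = config$margin_bp, seed = config$seed)
  genome <- generate_genome(gcfg)
  design <- generate_probe_design(genome, spacing = config$spacing,
                                  length_range = config$length_range,
                                  seed = config$seed + 1)
  truth <- spike_dmrs(genome, n = config$n_spiked_dmrs,
                      effect_m = config$effect_m,
                      width_bp = config$spike_width_bp,
                      seed = config$seed + 2)
  raw <- simulate_medip_arrays(design, truth,
                               array_sim_params(n_hybridizations = config$n_hybridizations,
                                                noise_sd = config$noise_sd,
                                                seed = config$seed + 3))
  ma <- to_ma(raw)
  ma <- gc_binned_loess(ma, n_bins = config$n_bins, span = config$span)
  ma <- quantile_normalize_A(ma)
  profiles <- pair_profiles(ma, window_bp = config$window_bp,
                            min_probes = config$min_probes,
                            smooth_scope = config$smooth_scope)
  dmrs <- call_dmrs(profiles, genome, probe_p = config$probe_p,
                    region_p = config$region_p, gap_bp = config$gap_bp,
                    intensity_floor = config$intensity_floor,
                    density_floor = config$density_floor)
  expr <- simulate_expression_matrix(
    expression_sim_params(n_genes = config$n_genes,
                          n_de_genes = config$n_de_genes,
                          seed = config$seed + 4))
  de <- de_filter(expr$matrix, expr$groups,
                  ratio_threshold = config$ratio_threshold,
                  diff_threshold = config$diff_threshold,
                  p_threshold = config$p_threshold)
  # map expression genes onto genome promoters by index for integration;
  # genes beyond the promoter catalog have no position and are skipped
  prom <- genome$promoters
  catalog <- data.frame(gene = prom$gene_symbol, chrom = prom$chrom,
                        pos = prom$tss, stringsAsFactors = FALSE)
  de_genes <- de$gene[de$passes]
  de_positions <- catalog[catalog$gene %in% de_genes, , drop = FALSE]
  overlap <- promoter_overlap(
    dmr_genes = unique(dmrs$gene_symbol[dmrs$gene_symbol != "intergenic"]),
    de_genes = de_genes, n_promoters = config$n_genes)
  ecrs <- ecr_scan(de_positions, catalog,
                   setNames(genome$chromosomes$length, genome$chromosomes$chrom),
                   window_range = config$ecr_window_range,
                   step_bp = config$ecr_step,
                   min_genes = config$ecr_min_genes, alpha = config$ecr_alpha)
  eo <- dmr_ecr_overlap(dmrs, ecrs)
  plot_table <- chromosome_plot_data(dmrs, de_positions, ecrs,
                                     setNames(genome$chromosomes$length,
                                              genome$chromosomes$chrom))
  result <- list(genome = genome, design = design, truth = truth, raw = raw,
                 ma = ma, profiles = profiles, dmrs = dmrs, expression = expr,
                 de = de, overlap = overlap, ecrs = ecrs, ecr_overlap = eo,
                 plot_table = plot_table, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  write_config(cfg[vapply(cfg, function(v) is.atomic(v) && length(v) == 1,
                          logical(1))],
               file.path(out_dir, "config.txt"))
  write_gff3_promoters(result$genome, file.path(out_dir, "promoters.gff3"))
  prom_bed <- result$genome$promoters
  prom_bed$start <- prom_bed$window_start
  prom_bed$end <- prom_bed$window_end
  write_bed6(prom_bed, file.path(out_dir, "promoters.bed"),
             name = "gene_symbol", strand = "strand")
  write_probe_design(result$design, file.path(out_dir, "probes.tsv"))
  if (nrow(result$truth)) {
    write.table(result$truth, file.path(out_dir, "truth_dmrs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (ch in c("cy3", "cy5")) {
    write.table(result$raw[[ch]], file.path(out_dir, paste0(ch, ".tsv")),
                sep = "\t", quote = FALSE)
  }
  for (id in names(result$profiles)) {
    write.table(result$profiles[[id]],
                file.path(out_dir, paste0("profile_", gsub("\\+", "_", id), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  dmrs <- result$dmrs
  write.table(dmrs, file.path(out_dir, "dmrs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(dmrs)) {
    dmrs$score <- pmin(1000, round(-log10(pmax(dmrs$region_p, 1e-300))))
    dmrs$strand_sym <- ifelse(dmrs$sign > 0, "+", "-")
    write_bed6(dmrs, file.path(out_dir, "dmrs.bed"), name = "gene_symbol",
               score = "score", strand = "strand_sym")
  }
  write.table(result$de, file.path(out_dir, "de_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$overlap, file.path(out_dir, "overlap.json"),
                       auto_unbox = TRUE, digits = NA)
  if (nrow(result$ecrs)) {
    write_bed6(result$ecrs, file.path(out_dir, "ecrs.bed"))
  }
  write.table(result$plot_table, file.path(out_dir, "chromosome_plot.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = cfg$seed, preset = cfg$preset,
                            n_sites = attr(result$dmrs, "n_sites"),
                            pair_counts = as.list(attr(result$dmrs, "pair_counts")),
                            package_version = as.character(utils::packageVersion("medipdmr"))),
                       file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Match called regions against a truth table of planted intervals
#'
#' A called region hits a truth interval when their Jaccard index (length of
#' intersection over length of union) is at least `min_jaccard`.  Recall is
#' the fraction of truth intervals hit; precision the fraction of calls
#' hitting some truth interval.
#'
#' @param called data.frame with chrom, start, end.
#' @param truth data.frame with chrom, start, end.
#' @param min_jaccard hit threshold (default 0.5).
#' @return list: recall, precision, n_called, n_truth.
#' @export
interval_recovery <- function(called, truth, min_jaccard = 0.5) {
  jac <- function(s1, e1, s2, e2) {
    inter <- max(0, min(e1, e2) - max(s1, s2))
    inter / (max(e1, e2) - min(s1, s2))
  }
  hit_truth <- rep(FALSE, nrow(truth))
  hit_call <- rep(FALSE, max(nrow(called), 0))
  if (nrow(called) && nrow(truth)) {
    for (i in seq_len(nrow(called))) {
      for (j in seq_len(nrow(truth))) {
        if (called$chrom[i] == truth$chrom[j] &&
            jac(called$start[i], called$end[i],
                truth$start[j], truth$end[j]) >= min_jaccard) {
          hit_truth[j] <- TRUE
          hit_call[i] <- TRUE
        }
      }
    }
  }
  list(recall = if (nrow(truth)) mean(hit_truth) else NA_real_,
       precision = if (nrow(called)) mean(hit_call) else NA_real_,
       n_called = nrow(called), n_truth = nrow(truth))
}
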