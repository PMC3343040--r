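#' Expected random overlap between two gene lists
#'
#' Under random draws from a common promoter universe, the expected number of
#' shared genes between a list of `n_dmr` and a list of `n_de` genes is the
#' hypergeometric mean `n_dmr * n_de / n_promoters`.  When an observed count
#' is supplied, a two-sided hypergeometric p-value (sum of outcome
#' probabilities no larger than the observed one) is returned alongside.
#'
#' @param n_dmr,n_de sizes of the two gene lists.
#' @param n_promoters size of the shared universe (e.g. 15,287 scanned
#'   promoters).
#' @param observed optional observed overlap count.
#' @return list with `expected` and, when `observed` is given, `p`.
#' @export
expected_random_overlap <- function(n_dmr, n_de, n_promoters, observed = NULL) {
  stopifnot(n_promoters > 0, n_dmr >= 0, n_de >= 0,
            n_dmr <= n_promoters, n_de <= n_promoters)
  expected <- n_dmr * n_de / n_promoters
  out <- list(expected = expected)
  if (!is.null(observed)) {
    stopifnot(observed >= 0, observed <= min(n_dmr, n_de))
    k <- max(0, n_dmr + n_de - n_promoters):min(n_dmr, n_de)
    dens <- dhyper(k, n_de, n_promoters - n_de, n_dmr)
    out$p <- min(1, sum(dens[dens <= dhyper(observed, n_de, n_promoters - n_de,
                                            n_dmr) * (1 + 1e-8)]))
  }
  out
}

#' Overlap between DMR-annotated genes and differentially expressed genes
#'
#' Intersects the two symbol lists case-insensitively, deduplicating each
#' (with a warning) first, and reports the observed overlap next to the
#' expected random overlap and its hypergeometric p-value.
#'
#' @param dmr_genes character vector of DMR gene symbols.
#' @param de_genes character vector of DE gene symbols.
#' @param n_promoters promoter universe size.
#' @return list: n_dmr, n_de, n_promoters, observed_overlap,
#'   overlapping_genes (original DMR-list casing), expected_overlap, p.
#' @export
promoter_overlap <- function(dmr_genes, de_genes, n_promoters) {
  dedup <- function(x, label) {
    lx <- tolower(x)
    if (anyDuplicated(lx)) {
      warning(sprintf("duplicate symbols in %s list deduplicated", label))
      x <- x[!duplicated(lx)]
    }
    x
  }
  dmr_genes <- dedup(dmr_genes, "DMR")
  de_genes <- dedup(de_genes, "DE")
  hit <- tolower(dmr_genes) %in% tolower(de_genes)
  ero <- expected_random_overlap(length(dmr_genes), length(de_genes),
                                 n_promoters, observed = sum(hit))
  list(n_dmr = length(dmr_genes), n_de = length(de_genes),
       n_promoters = n_promoters, observed_overlap = sum(hit),
       overlapping_genes = dmr_genes[hit],
       expected_overlap = ero$expected, p = ero$p)
}

#' Scan for megabase-scale clusters of differentially expressed genes
#'
#' Slides windows of every size in `window_range` (swept in `step_bp`
#' increments) along each chromosome in `step_bp` steps and scores each
#' window's DE-gene count against a one-sided binomial with success
#' probability equal to the genome-wide DE fraction of the gene catalog.
#' Windows with p below `alpha` and at least `min_genes` DE genes are kept;
#' overlapping significant windows are merged into the smallest interval
#' covering them, and the merged span is re-scored.
#'
#' @param de_positions data.frame (gene, chrom, pos) of DE genes.
#' @param catalog data.frame (gene, chrom, pos) of all genes with positions
#'   (the background); must contain the DE genes.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window_range numeric length-2, min and max window size in bp
#'   (default 2–5 Mb).
#' @param step_bp slide/sweep step (default 0.5 Mb).
#' @param min_genes minimum DE genes per reported window (default 4).
#' @param alpha significance level (default 0.05).
#' @return data.frame of merged windows: chrom, start, end, n_de_genes,
#'   n_catalog_genes, expected, p; deterministic order (chrom, start).
#' @export
ecr_scan <- function(de_positions, catalog, chrom_lengths,
                     window_range = c(2e6, 5e6), step_bp = 5e5,
                     min_genes = 4L, alpha = 0.05) {
  stopifnot(all(c("gene", "chrom", "pos") %in% names(de_positions)),
            all(c("gene", "chrom", "pos") %in% names(catalog)),
            window_range[1] <= window_range[2], step_bp > 0)
  missing_pos <- !is.finite(de_positions$pos)
  if (any(missing_pos)) {
    warning(sprintf("%d DE genes without positions skipped", sum(missing_pos)))
    de_positions <- de_positions[!missing_pos, , drop = FALSE]
  }
  p0 <- nrow(de_positions) / nrow(catalog)
  sizes <- seq(window_range[1], window_range[2], by = step_bp)
  score_window <- function(ch, s, e) {
    g <- sum(catalog$chrom == ch & catalog$pos >= s & catalog$pos < e)
    k <- sum(de_positions$chrom == ch & de_positions$pos >= s & de_positions$pos < e)
    p <- if (g == 0) 1 else pbinom(k - 1, g, p0, lower.tail = FALSE)
    list(g = g, k = k, p = p)
  }
  hits <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    for (w in sizes) {
      if (w > len) next
      starts <- seq(0, len - w, by = step_bp)
      for (s in starts) {
        sc <- score_window(ch, s, s + w)
        if (sc$k >= min_genes && sc$p < alpha) {
          hits[[length(hits) + 1L]] <- data.frame(chrom = ch, start = s,
                                                  end = s + w)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_de_genes = integer(), n_catalog_genes = integer(),
                      expected = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, hits)
  hits <- hits[order(hits$chrom, hits$start, hits$end), ]
  merged <- list()
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch, ]
    cur_s <- h$start[1]; cur_e <- h$end[1]
    for (i in seq_len(nrow(h))[-1]) {
      if (h$start[i] < cur_e) {
        cur_e <- max(cur_e, h$end[i])
      } else {
        merged[[length(merged) + 1L]] <- c(ch, cur_s, cur_e)
        cur_s <- h$start[i]; cur_e <- h$end[i]
      }
    }
    merged[[length(merged) + 1L]] <- c(ch, cur_s, cur_e)
  }
  out <- do.call(rbind, lapply(merged, function(m) {
    sc <- score_window(m[1], as.numeric(m[2]), as.numeric(m[3]))
    data.frame(chrom = m[1], start = as.numeric(m[2]), end = as.numeric(m[3]),
               n_de_genes = sc$k, n_catalog_genes = sc$g,
               expected = sc$g * p0, p = sc$p, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Overlap of DMRs with DE-gene cluster windows
#'
#' An ECR window counts as overlapped when at least one DMR interval
#' intersects it (0-based half-open intervals; touching endpoints do not
#' overlap).
#'
#' @param dmrs data.frame with chrom, start, end.
#' @param ecrs data.frame with chrom, start, end.
#' @return list with `n_overlapped_ecrs` and `pairs` (data.frame of ecr_index,
#'   dmr_index).
#' @export
dmr_ecr_overlap <- function(dmrs, ecrs) {
  if (!nrow(dmrs) || !nrow(ecrs)) {
    return(list(n_overlapped_ecrs = 0L,
                pairs = data.frame(ecr_index = integer(), dmr_index = integer())))
  }
  lev <- unique(c(dmrs$chrom, ecrs$chrom))
  gd <- GenomicRanges::GRanges(factor(dmrs$chrom, levels = lev),
                               IRanges::IRanges(dmrs$start + 1, dmrs$end))
  ge <- GenomicRanges::GRanges(factor(ecrs$chrom, levels = lev),
                               IRanges::IRanges(ecrs$start + 1, ecrs$end))
  hits <- GenomicRanges::findOverlaps(ge, gd)
  pairs <- data.frame(ecr_index = S4Vectors::queryHits(hits),
                      dmr_index = S4Vectors::subjectHits(hits))
  list(n_overlapped_ecrs = length(unique(pairs$ecr_index)), pairs = pairs)
}

#' Feature table for a chromosome (karyogram) plot
#'
#' Stacks DMRs, DE-gene positions, and ECR windows into one typed interval
#' table suitable for rendering a per-chromosome ideogram track.
#'
#' @param dmrs data.frame with chrom, start, end (may be empty).
#' @param de_positions data.frame with chrom, pos (may be empty); each gene
#'   becomes a 1 bp tick.
#' @param ecrs data.frame with chrom, start, end (may be empty).
#' @param chrom_lengths optional named vector; features beyond a chromosome's
#'   length raise an error.
#' @return data.frame: type ("DMR"/"DE"/"ECR"), chrom, start, end.
#' @export
chromosome_plot_data <- function(dmrs = NULL, de_positions = NULL, ecrs = NULL,
                                 chrom_lengths = NULL) {
  piece <- function(df, type, start, end) {
    if (is.null(df) || !nrow(df)) return(NULL)
    data.frame(type = type, chrom = df$chrom, start = start, end = end,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    piece(dmrs, "DMR", dmrs$start, dmrs$end),
    piece(de_positions, "DE", de_positions$pos, de_positions$pos + 1),
    piece(ecrs, "ECR", ecrs$start, ecrs$end))
  if (is.null(out)) {
    out <- data.frame(type = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(chrom_lengths) && nrow(out)) {
    bad <- !(out$chrom %in% names(chrom_lengths)) |
      out$end > chrom_lengths[out$chrom]
    if (any(bad)) stop("feature beyond chromosome length")
  }
  rownames(out) <- NULL
  out
}

#' Convert a body dose to a molar concentration
#'
#' Assuming a whole-body volume of distribution, a dose in mg/kg corresponds
#' to `1000 * dose / (molar_mass * vd)` micromolar.  With vinclozolin
#' (molar mass 286.11 g/mol) a 100 mg/kg dose converts to about 350 uM.
#'
#' @param dose_mg_per_kg dose in mg per kg body weight.
#' @param molar_mass_g_per_mol compound molar mass.
#' @param vd_L_per_kg volume of distribution in L/kg (default 1, whole body).
#' @return concentration in micromolar.
#' @export
dose_to_micromolar <- function(dose_mg_per_kg, molar_mass_g_per_mol,
                               vd_L_per_kg = 1.0) {
  stopifnot(dose_mg_per_kg > 0, molar_mass_g_per_mol > 0, vd_L_per_kg > 0)
  1000 * dose_mg_per_kg / (molar_mass_g_per_mol * vd_L_per_kg)
}

#' Molar mass of vinclozolin (g/mol), used in the dose-conversion example
#' @export
VINCLOZOLIN_MOLAR_MASS <- 286.11
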