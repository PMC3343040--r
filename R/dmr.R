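#' Intersect per-pair significant probes
#'
#' A probe becomes a significant site only when its p-value is below
#' `p_threshold` in every paired analysis and the sign of its smoothed M
#' agrees across all pairs — the stringent all-pairs reproducibility rule.
#' Per-pair significant-probe counts are attached as the `pair_counts`
#' attribute.
#'
#' @param profiles list of per-pair profiles from [pair_profiles()]; all must
#'   cover the identical probe set.
#' @param p_threshold probe-level significance threshold (default 1e-5).
#' @return data.frame of sites: probe_id, chrom, start, end, sign, mean_Z
#'   (across pairs), max_p (worst pair), mean_smoothed_A; sorted by
#'   (chrom, start).
#' @export
intersect_pairs <- function(profiles, p_threshold = 1e-5) {
  stopifnot(length(profiles) >= 1, p_threshold > 0)
  ids <- lapply(profiles, `[[`, "probe_id")
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]]))) {
    stop("paired profiles cover different probe sets")
  }
  base <- profiles[[1]][c("probe_id", "chrom", "start", "end")]
  P <- vapply(profiles, `[[`, numeric(nrow(base)), "p")
  S <- vapply(profiles, function(pr) sign(pr$smoothed_M), numeric(nrow(base)))
  Z <- vapply(profiles, `[[`, numeric(nrow(base)), "Z")
  A <- vapply(profiles, `[[`, numeric(nrow(base)), "smoothed_A")
  P <- matrix(P, nrow = nrow(base)); S <- matrix(S, nrow = nrow(base))
  Z <- matrix(Z, nrow = nrow(base)); A <- matrix(A, nrow = nrow(base))
  pass <- rowSums(P < p_threshold, na.rm = TRUE) == ncol(P) &
    apply(P, 1, function(x) all(is.finite(x)))
  same_sign <- apply(S, 1, function(x) all(is.finite(x)) && all(x == x[1]) && x[1] != 0)
  keep <- which(pass & same_sign)
  out <- cbind(base[keep, , drop = FALSE],
               data.frame(sign = as.integer(S[keep, 1]),
                          mean_Z = rowMeans(Z[keep, , drop = FALSE]),
                          max_p = apply(P[keep, , drop = FALSE], 1, max),
                          mean_smoothed_A = rowMeans(A[keep, , drop = FALSE])))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pair_counts") <- colSums(P < p_threshold, na.rm = TRUE)
  out
}

stouffer_p <- function(z) {
  zc <- sum(z) / sqrt(length(z))
  2 * pnorm(-abs(zc))
}

fisher_p <- function(p) {
  stat <- -2 * sum(log(pmax(p, .Machine$double.xmin)))
  pchisq_upper <- stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
  pchisq_upper
}

#' Cluster consecutive significant sites into candidate regions
#'
#' Consecutive sites on the same chromosome with the same sign of smoothed M
#' are combined into one region when the gap from the previous site's end to
#' the next site's start is at most `gap_bp`.  Region significance combines
#' the sites' mean-across-pairs Z-scores (Stouffer by default; Fisher on the
#' per-site worst-pair p-values as an alternative).  Singleton regions are
#' allowed.
#'
#' @param sites data.frame from [intersect_pairs()], sorted by (chrom, start).
#' @param gap_bp maximum merge gap in bp (end-to-start, default 600).
#' @param combine `"stouffer"` or `"fisher"`.
#' @return data.frame of regions: chrom, start, end, region_size, sign,
#'   region_p, mean_A, n_probes (0-based half-open; region_size = end − start).
#' @export
cluster_regions <- function(sites, gap_bp = 600, combine = c("stouffer", "fisher")) {
  combine <- match.arg(combine)
  if (!nrow(sites)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      region_size = numeric(), sign = integer(),
                      region_p = numeric(), mean_A = numeric(),
                      n_probes = integer(), stringsAsFactors = FALSE))
  }
  if (is.unsorted(order(sites$chrom, sites$start)) ||
      any(diff(order(sites$chrom, sites$start)) != 1)) {
    stop("sites must be sorted by (chrom, start)")
  }
  new_cluster <- c(TRUE,
                   sites$chrom[-1] != sites$chrom[-nrow(sites)] |
                   sites$sign[-1] != sites$sign[-nrow(sites)] |
                   (sites$start[-1] - sites$end[-nrow(sites)]) > gap_bp)
  grp <- cumsum(new_cluster)
  regions <- do.call(rbind, lapply(split(seq_len(nrow(sites)), grp), function(i) {
    s <- sites[i, ]
    p <- if (combine == "stouffer") stouffer_p(s$mean_Z) else fisher_p(s$max_p)
    data.frame(chrom = s$chrom[1], start = min(s$start), end = max(s$end),
               region_size = max(s$end) - min(s$start),
               sign = s$sign[1], region_p = p,
               mean_A = mean(s$mean_smoothed_A),
               n_probes = nrow(s), stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  regions
}

count_cpgs <- function(regions, cpg) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(cpg$chrom == regions$chrom[i] &
          cpg$pos >= regions$start[i] & cpg$pos < regions$end[i])
  }, numeric(1))
}

#' Filter candidate regions on intensity and CpG density
#'
#' Keeps regions whose mean smoothed intensity (A, log2 scale) exceeds
#' `intensity_floor` and whose CpG density (100 · CpG count / region size) is
#' at least `density_floor`.  Both values are recorded on every input region
#' before filtering.
#'
#' @param regions data.frame from [cluster_regions()].
#' @param genome a `genome_model` supplying the CpG map and chromosome bounds.
#' @param intensity_floor minimum mean A (strict, default 9.5).
#' @param density_floor minimum CpGs per 100 bp (inclusive, default 1).
#' @return the surviving regions with `cpg_count` and `cpg_density` columns.
#' @export
filter_regions <- function(regions, genome, intensity_floor = 9.5,
                           density_floor = 1) {
  stopifnot(inherits(genome, "genome_model"))
  if (!nrow(regions)) {
    regions$cpg_count <- numeric()
    regions$cpg_density <- numeric()
    return(regions)
  }
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  unknown <- !(regions$chrom %in% names(lens))
  beyond <- !unknown & regions$end > lens[regions$chrom]
  if (any(unknown | beyond)) {
    stop("region outside CpG map coverage: ",
         paste(regions$chrom[unknown | beyond], collapse = ", "))
  }
  regions$cpg_count <- count_cpgs(regions, genome$cpg)
  regions$cpg_density <- 100 * regions$cpg_count / regions$region_size
  keep <- regions$mean_A > intensity_floor & regions$cpg_density >= density_floor
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate regions with their promoter gene
#'
#' Assigns each region the gene whose promoter window contains the region
#' midpoint; when several windows contain it, the gene with the nearest TSS
#' wins.  Regions in no promoter window are labelled `"intergenic"`.
#'
#' @param regions data.frame of regions (chrom, start, end, ...).
#' @param genome a `genome_model`.
#' @return the regions with `gene_symbol` and `entrez_id` columns.
#' @export
annotate_regions <- function(regions, genome) {
  stopifnot(inherits(genome, "genome_model"))
  if (!nrow(regions)) {
    regions$gene_symbol <- character()
    regions$entrez_id <- integer()
    return(regions)
  }
  p <- genome$promoters
  mid <- (regions$start + regions$end) / 2
  # 0-based half-open -> 1-based closed for IRanges
  q <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(floor(mid) + 1, floor(mid) + 1))
  s <- GenomicRanges::GRanges(p$chrom,
                              IRanges::IRanges(p$window_start + 1, p$window_end))
  hits <- GenomicRanges::findOverlaps(q, s)
  gene <- rep("intergenic", nrow(regions))
  entrez <- rep(NA_integer_, nrow(regions))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in unique(qh)) {
    cand <- sh[qh == i]
    best <- cand[which.min(abs(p$tss[cand] - mid[i]))]
    gene[i] <- p$gene_symbol[best]
    entrez[i] <- p$entrez_id[best]
  }
  regions$gene_symbol <- gene
  regions$entrez_id <- entrez
  regions
}

#' Call differentially methylated regions from per-pair profiles
#'
#' Runs the full calling chain: all-pairs intersection of significant probes,
#' clustering of consecutive same-sign sites, the optional region-level
#' significance threshold, intensity and CpG-density filters, and promoter
#' annotation.
#'
#' @param profiles list from [pair_profiles()].
#' @param genome a `genome_model`.
#' @param probe_p probe-level p threshold applied in every pair (default 1e-5).
#' @param region_p region-level combined-significance ceiling (default 1e-7;
#'   `NULL` disables it).
#' @param gap_bp cluster merge gap (default 600).
#' @param intensity_floor minimum mean A (default 9.5, log scale).
#' @param density_floor minimum CpG density per 100 bp (default 1).
#' @return annotated data.frame of reported DMRs; attributes `pair_counts`
#'   and `n_sites` record intermediate tallies.
#' @export
call_dmrs <- function(profiles, genome, probe_p = 1e-5, region_p = 1e-7,
                      gap_bp = 600, intensity_floor = 9.5, density_floor = 1) {
  sites <- intersect_pairs(profiles, probe_p)
  regions <- cluster_regions(sites, gap_bp)
  if (!is.null(region_p) && nrow(regions)) {
    regions <- regions[regions$region_p <= region_p, , drop = FALSE]
  }
  regions <- filter_regions(regions, genome, intensity_floor, density_floor)
  regions <- annotate_regions(regions, genome)
  attr(regions, "pair_counts") <- attr(sites, "pair_counts")
  attr(regions, "n_sites") <- nrow(sites)
  regions
}
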