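# Build a list of per-pair profiles directly, bypassing simulation, so the
# intersection logic can be pinned down probe by probe.
toy_profiles <- function(p_mat, m_mat, a = 10) {
  n <- nrow(p_mat)
  lapply(seq_len(ncol(p_mat)), function(j) {
    data.frame(probe_id = sprintf("P%03d", seq_len(n)),
               chrom = "chr1", start = seq_len(n) * 1000,
               end = seq_len(n) * 1000 + 60,
               smoothed_M = m_mat[, j], smoothed_A = a,
               Z = m_mat[, j] * 10, p = p_mat[, j],
               stringsAsFactors = FALSE)
  })
}

test_that("site retention requires significance and sign agreement in all pairs", {
  p <- matrix(1e-6, 3, 3)
  p[1, 3] <- 1e-3                       # probe 1 misses one pair
  m <- matrix(1, 3, 3)
  m[2, 3] <- -1                         # probe 2 flips sign in one pair
  sites <- intersect_pairs(toy_profiles(p, m), p_threshold = 1e-5)
  expect_equal(sites$probe_id, "P003")
  expect_equal(sites$sign, 1L)
  expect_equal(unname(attr(sites, "pair_counts")), c(3L, 3L, 2L))

  # mismatched probe sets rejected
  bad <- toy_profiles(p, m)
  bad[[2]] <- bad[[2]][-1, ]
  expect_error(intersect_pairs(bad), "different probe sets")
})

test_that("threshold monotonicity: relaxing the probe p cutoff never loses sites", {
  set.seed(5)
  p <- matrix(10^runif(300, -8, 0), 100, 3)
  m <- matrix(rep(sample(c(-1, 1), 100, TRUE), 3), 100, 3)
  profs <- toy_profiles(p, m)
  n_strict <- nrow(intersect_pairs(profs, 1e-6))
  n_loose <- nrow(intersect_pairs(profs, 1e-4))
  expect_gte(n_loose, n_strict)
})

test_that("region clustering merges by gap, sign and chromosome", {
  sites <- data.frame(probe_id = c("a", "b", "c"), chrom = "chr1",
                      start = c(0, 661, 2000), end = c(60, 721, 2060),
                      sign = c(1L, 1L, 1L), mean_Z = 6, max_p = 1e-8,
                      mean_smoothed_A = 10, stringsAsFactors = FALSE)
  # gap a->b = 601 bp: two regions; exactly 600 merges
  r <- cluster_regions(sites, gap_bp = 600)
  expect_equal(nrow(r), 3L)
  sites$start[2] <- 660
  r <- cluster_regions(sites, gap_bp = 600)
  expect_equal(nrow(r), 2L)
  expect_equal(r$region_size, r$end - r$start)

  # opposite signs never merge even at zero gap
  sites$sign <- c(1L, -1L, 1L)
  r2 <- cluster_regions(sites, gap_bp = 600)
  expect_equal(nrow(r2), 3L)
})

test_that("region clustering matches the transitive-closure oracle", {
  for (s in 1:100) {
    sites <- random_sites(15, seed = 3000 + s)
    got <- cluster_regions(sites, gap_bp = 600)
    want <- oracle_cluster_spans(sites, gap_bp = 600)
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_probes, want$n)
  }
})

test_that("region significance aggregates evidence across probes", {
  sites <- data.frame(probe_id = letters[1:4], chrom = "chr1",
                      start = c(0, 100, 200, 300), end = c(60, 160, 260, 360),
                      sign = 1L, mean_Z = c(5, 5, 5, 5), max_p = 1e-7,
                      mean_smoothed_A = 10, stringsAsFactors = FALSE)
  r <- cluster_regions(sites)
  # Stouffer: Z_c = 4*5/sqrt(4) = 10
  expect_equal(r$region_p, 2 * pnorm(-10), tolerance = 1e-12)
  rf <- cluster_regions(sites, combine = "fisher")
  expect_lt(rf$region_p, 1e-7)
})

test_that("intensity and CpG-density filters apply the stated floors", {
  g <- tiny_genome(n_promoters = 2L, seed = 31L)
  # hand-built CpG map: 5 CpGs then 6 CpGs over two 600 bp regions
  w <- g$promoters$window_start
  g$cpg <- data.frame(chrom = g$promoters$chrom[c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2)],
                      pos = c(w[1] + seq(0, 400, by = 100),
                              w[2] + seq(0, 500, by = 100)))
  g$cpg <- g$cpg[order(g$cpg$chrom, g$cpg$pos), ]
  regions <- data.frame(chrom = g$promoters$chrom, start = w, end = w + 600,
                        region_size = 600, sign = 1L, region_p = 1e-20,
                        mean_A = c(9.4, 10), n_probes = 3L,
                        stringsAsFactors = FALSE)
  # region 1: mean_A 9.4 < 9.5 drops it regardless of density
  kept <- filter_regions(regions, g)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$cpg_count, 6)
  expect_equal(kept$cpg_density, 1)     # 6 CpG / 600 bp = exactly the floor, kept
  # 5 CpGs in 600 bp = 0.833/100bp fails the density floor
  regions$mean_A <- c(10, 10)
  kept2 <- filter_regions(regions, g)
  expect_false(any(kept2$cpg_count == 5))
  # raising the intensity floor never adds regions
  expect_lte(nrow(filter_regions(regions, g, intensity_floor = 10.5)),
             nrow(filter_regions(regions, g, intensity_floor = 9.5)))
  # out-of-coverage regions are an error
  bad <- regions; bad$chrom <- "chrZ"
  expect_error(filter_regions(bad, g), "coverage")
})

test_that("regions are annotated to the promoter containing their midpoint", {
  g <- tiny_genome(n_promoters = 6L, seed = 41L)
  p <- g$promoters
  # region centred 1,000 bp upstream of promoter 1's TSS
  shift <- ifelse(p$strand[1] == "+", -1000, 1000)
  centre <- p$tss[1] + shift
  reg <- data.frame(chrom = p$chrom[1], start = centre - 300, end = centre + 300)
  ann <- annotate_regions(reg, g)
  expect_equal(ann$gene_symbol, p$gene_symbol[1])
  # region far from any promoter window
  gap_reg <- data.frame(chrom = p$chrom[1], start = 0, end = 10)
  expect_equal(annotate_regions(gap_reg, g)$gene_symbol, "intergenic")
})

test_that("overlapping promoter windows resolve to the nearest TSS", {
  g <- tiny_genome(n_promoters = 2L, seed = 43L)
  # force the two windows to overlap on one chromosome
  g$promoters$chrom <- c("chr1", "chr1")
  g$promoters$window_start <- c(10000, 12000)
  g$promoters$window_end <- c(14850, 16850)
  g$promoters$tss <- c(13880, 12970)
  g$promoters$strand <- c("+", "-")
  mid <- 13000                             # inside both; nearer TSS is 12970
  reg <- data.frame(chrom = "chr1", start = mid - 50, end = mid + 50)
  expect_equal(annotate_regions(reg, g)$gene_symbol, g$promoters$gene_symbol[2])
})

test_that("spiked DMRs are recovered end to end with correct annotation", {
  res <- run_pipeline(pipeline_config(seed = 3, n_promoters = 400L,
                                      n_spiked_dmrs = 10L))
  rec <- interval_recovery(res$dmrs, res$truth)
  expect_gte(rec$recall, 0.9)
  expect_gte(rec$precision, 0.9)
  # at least 9 of 10 annotated to the spiked promoter's gene
  hits <- sum(res$truth$gene_symbol %in% res$dmrs$gene_symbol)
  expect_gte(hits, 9)
  # sign of the call matches the planted direction for matched genes
  m <- merge(res$dmrs, res$truth, by = "gene_symbol",
             suffixes = c("_call", "_truth"))
  expect_true(all(m$sign_call == m$sign_truth))
})
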