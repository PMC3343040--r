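# Small builders and independent brute-force oracles shared across tests.

tiny_genome <- function(n_promoters = 10L, seed = 7L,
                        chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                        cpg_density_range = c(0.5, 3)) {
  generate_genome(genome_config(chrom_lengths = chrom_lengths,
                                n_promoters = n_promoters,
                                cpg_density_range = cpg_density_range,
                                seed = seed))
}

# Minimal ma_array wrapper around given matrices; gc_fraction drives binning.
make_ma <- function(M, A, gc_fraction = runif(nrow(as.matrix(M)), 0.3, 0.7)) {
  M <- as.matrix(M); A <- as.matrix(A)
  design <- structure(list(probes = data.frame(
    probe_id = sprintf("P%04d", seq_len(nrow(M))),
    chrom = "chr1",
    start = seq_len(nrow(M)) * 100,
    end = seq_len(nrow(M)) * 100 + 60,
    gc_fraction = gc_fraction)), class = "probe_design")
  structure(list(M = M, A = A, gc_bin = NULL, design = design, audit = list()),
            class = "ma_array")
}

make_raw <- function(cy3, cy5) {
  cy3 <- as.matrix(cy3); cy5 <- as.matrix(cy5)
  structure(list(cy3 = cy3, cy5 = cy5,
                 design = structure(list(probes = data.frame(
                   probe_id = sprintf("P%04d", seq_len(nrow(cy3))))),
                   class = "probe_design"),
                 truth = data.frame(), spiked = rep(FALSE, nrow(cy3)),
                 params = NULL),
            class = "raw_array_set")
}

# O(n^2) window-median oracle: for each probe, scan all probes on the same
# chromosome, collect values of those with midpoint in [mid - w/2, mid + w/2).
oracle_window_median <- function(values, chrom, start, end, window_bp, min_probes) {
  values <- as.matrix(values)
  mid <- (start + end) / 2
  out <- rep(NA_real_, nrow(values))
  for (i in seq_len(nrow(values))) {
    sel <- which(chrom == chrom[i] &
                   mid >= mid[i] - window_bp / 2 &
                   mid < mid[i] + window_bp / 2)
    v <- values[sel, , drop = FALSE]
    present <- apply(v, 1, function(x) any(is.finite(x)))
    if (sum(present) < min_probes) next
    out[i] <- median(v[is.finite(v)])
  }
  out
}

# Independent clustering oracle: mark consecutive sorted sites mergeable, take
# transitive closure over a boolean adjacency matrix.
oracle_cluster_spans <- function(sites, gap_bp) {
  n <- nrow(sites)
  if (!n) return(data.frame(start = numeric(), end = numeric()))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    j <- i + 1
    adj[i, j] <- adj[j, i] <- sites$chrom[i] == sites$chrom[j] &&
      sites$sign[i] == sites$sign[j] &&
      (sites$start[j] - sites$end[i]) <= gap_bp
  }
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ix) {
    data.frame(chrom = sites$chrom[ix[1]],
               start = min(sites$start[ix]), end = max(sites$end[ix]),
               n = length(ix))
  }))
  out[order(out$chrom, out$start), ]
}

# All-pairs interval intersection oracle (0-based half-open).
oracle_overlap_pairs <- function(a, b) {
  hits <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
          a$end[i] > b$start[j]) {
        hits[[length(hits) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(data.frame(a = integer(), b = integer()))
  m <- do.call(rbind, hits)
  data.frame(a = m[, 1], b = m[, 2])
}

# Random toy site table for clustering/intersection oracles; gaps are drawn
# around the 600 bp merge threshold so both outcomes occur.
random_sites <- function(n, seed) {
  set.seed(seed)
  start <- sample.int(1200, n, replace = TRUE)  # gap increments 0-1200 bp
  df <- data.frame(probe_id = sprintf("P%03d", seq_len(n)),
                   chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                   sign = sample(c(-1L, 1L), n, replace = TRUE),
                   mean_Z = rnorm(n, 6), max_p = runif(n, 0, 1e-6),
                   mean_smoothed_A = runif(n, 9, 12),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom), ]
  pos <- unlist(lapply(split(start, df$chrom), function(g) cumsum(g + 60)))
  df$start <- pos
  df$end <- pos + 60
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  df
}
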