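#' Generate a promoter tiling probe design
#'
#' Tiles each promoter window with probes at a fixed start-to-start spacing
#' (default 100 bp, the array's median spacing) and lengths drawn uniformly
#' from `length_range` (default 50–75-mer).  Every promoter receives at least
#' one probe even when the spacing exceeds the window.  Each probe's GC count
#' is consistent with the genome's CpG map: every CpG dinucleotide inside a
#' probe contributes one G and one C (hence 2 to gc_count); remaining bases
#' contribute G/C at a background rate.
#'
#' @param genome a `genome_model`.
#' @param spacing start-to-start probe spacing in bp.
#' @param length_range integer vector of length 2, min and max probe length.
#' @param gc_background probability that a non-CpG base is G or C.
#' @param seed RNG seed.
#' @return a list of class `probe_design` with `probes` (data.frame: probe_id,
#'   chrom, start, end, length, gc_count, gc_fraction, n_cpg, promoter_index),
#'   `spacing_median`, `length_range`, and a reference to `genome`.
#' @export
generate_probe_design <- function(genome, spacing = 100L,
                                  length_range = c(50L, 75L),
                                  gc_background = 0.4, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), spacing > 0,
            length(length_range) == 2, length_range[1] <= length_range[2],
            length_range[1] > 0)
  p <- genome$promoters
  cpg_by_chrom <- split(genome$cpg$pos, genome$cpg$chrom)
  with_seed(seed, {
    rows <- vector("list", nrow(p))
    for (i in seq_len(nrow(p))) {
      ws <- p$window_start[i]; we <- p$window_end[i]
      starts <- seq(ws, max(ws, we - length_range[2]), by = spacing)
      len <- if (length_range[1] == length_range[2]) {
        rep(length_range[1], length(starts))
      } else {
        sample(seq(length_range[1], length_range[2]), length(starts), replace = TRUE)
      }
      end <- pmin(starts + len, we)
      # CpG dinucleotide fully inside the probe: start <= pos, pos+2 <= end
      cp <- cpg_by_chrom[[p$chrom[i]]] %||% numeric()
      n_cpg <- vapply(seq_along(starts), function(j) {
        sum(cp >= starts[j] & cp + 2 <= end[j])
      }, numeric(1))
      width <- end - starts
      extra <- rbinom(length(starts), pmax(width - 2 * n_cpg, 0), gc_background)
      gc <- 2 * n_cpg + extra
      rows[[i]] <- data.frame(chrom = p$chrom[i], start = starts, end = end,
                              length = width, gc_count = gc,
                              gc_fraction = gc / width, n_cpg = n_cpg,
                              promoter_index = i, stringsAsFactors = FALSE)
    }
    probes <- do.call(rbind, rows)
    probes <- probes[order(probes$chrom, probes$start), , drop = FALSE]
    rownames(probes) <- NULL
    probes <- cbind(probe_id = sprintf("P%06d", seq_len(nrow(probes))), probes,
                    stringsAsFactors = FALSE)
    mids <- (probes$start + probes$end) / 2
    gaps <- unlist(lapply(split(probes$start, probes$promoter_index), diff),
                   use.names = FALSE)
    design <- list(probes = probes,
                   spacing_median = if (length(gaps)) median(gaps) else NA_real_,
                   length_range = as.integer(length_range),
                   genome = genome)
    class(design) <- "probe_design"
    design
  })
}

probe_midpoints <- function(design) {
  (design$probes$start + design$probes$end) / 2
}
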