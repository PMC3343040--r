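#' Promoter window half-widths used by the tiling design
#'
#' Promoter windows extend 3,880 bp upstream and 970 bp downstream of the
#' transcription start site (4,850 bp total), matching the promoter tiling
#' array the pipeline targets.
#' @export
PROMOTER_UPSTREAM <- 3880L

#' @rdname PROMOTER_UPSTREAM
#' @export
PROMOTER_DOWNSTREAM <- 970L

#' Configuration for the synthetic genome model
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param n_promoters number of promoters to place.
#' @param cpg_density_range range (per 100 bp) from which each promoter's CpG
#'   density is drawn uniformly; densities straddling 1/100 bp exercise both
#'   sides of the CpG-density filter.
#' @param margin_bp minimum gap enforced between adjacent promoter windows.
#' @param seed RNG seed (mandatory).
#' @return a list of class `genome_config`.
#' @export
genome_config <- function(chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                          n_promoters = 100L,
                          cpg_density_range = c(0.5, 3),
                          margin_bp = 2000L,
                          seed = 1L) {
  stopifnot(all(chrom_lengths > 0), n_promoters >= 0,
            length(cpg_density_range) == 2, all(cpg_density_range >= 0),
            margin_bp >= 0)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  structure(list(chrom_lengths = chrom_lengths,
                 n_promoters = as.integer(n_promoters),
                 cpg_density_range = as.numeric(cpg_density_range),
                 margin_bp = as.integer(margin_bp),
                 seed = seed),
            class = "genome_config")
}

promoter_window <- function(tss, strand) {
  up <- ifelse(strand == "+", PROMOTER_UPSTREAM, PROMOTER_DOWNSTREAM)
  dn <- ifelse(strand == "+", PROMOTER_DOWNSTREAM, PROMOTER_UPSTREAM)
  data.frame(window_start = tss - up, window_end = tss + dn)
}

#' Generate a synthetic genome model for promoter tiling
#'
#' Places non-overlapping promoter windows (−3,880/+970 bp around each TSS,
#' strand-mirrored) on the configured chromosomes and draws CpG dinucleotide
#' positions inside each window at a per-promoter density sampled from
#' `cpg_density_range`.  Coordinates are 0-based half-open throughout.
#'
#' @param config a [genome_config()].
#' @return a list of class `genome_model` with elements `chromosomes`
#'   (data.frame: chrom, length), `promoters` (data.frame: gene_symbol,
#'   entrez_id, chrom, tss, strand, window_start, window_end, cpg_density),
#'   `cpg` (data.frame: chrom, pos; sorted), and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "genome_config"))
  lens <- config$chrom_lengths
  width <- PROMOTER_UPSTREAM + PROMOTER_DOWNSTREAM
  slot <- width + config$margin_bp
  capacity <- sum(floor(lens / slot))
  if (config$n_promoters > capacity) {
    stop(sprintf("cannot place %d promoters: chromosomes hold at most %d non-overlapping windows",
                 config$n_promoters, capacity))
  }
  with_seed(config$seed, {
    chromosomes <- data.frame(chrom = names(lens), length = as.numeric(lens),
                              stringsAsFactors = FALSE)
    n <- config$n_promoters
    if (n == 0L) {
      promoters <- data.frame(gene_symbol = character(), entrez_id = integer(),
                              chrom = character(), tss = numeric(),
                              strand = character(), window_start = numeric(),
                              window_end = numeric(), cpg_density = numeric(),
                              stringsAsFactors = FALSE)
      cpg <- data.frame(chrom = character(), pos = numeric())
    } else {
      # allocate promoters to chromosomes proportionally to slot capacity
      per_chrom <- floor(lens / slot)
      alloc <- integer(length(lens))
      order_cap <- order(per_chrom, decreasing = TRUE)
      remaining <- n
      share <- pmin(per_chrom, ceiling(n * per_chrom / sum(per_chrom)))
      for (i in order_cap) {
        take <- min(share[i], remaining, per_chrom[i])
        alloc[i] <- take
        remaining <- remaining - take
      }
      # top up if rounding left some unplaced
      i <- 1L
      while (remaining > 0L) {
        j <- order_cap[((i - 1L) %% length(lens)) + 1L]
        if (alloc[j] < per_chrom[j]) {
          alloc[j] <- alloc[j] + 1L
          remaining <- remaining - 1L
        }
        i <- i + 1L
      }
      rows <- vector("list", length(lens))
      idx0 <- 0L
      for (ci in seq_along(lens)) {
        k <- alloc[ci]
        if (k == 0L) next
        slots <- sort(sample.int(floor(lens[ci] / slot), k))
        jitter <- floor(runif(k, 0, config$margin_bp + 1))
        window_start <- (slots - 1) * slot + jitter
        strand <- sample(c("+", "-"), k, replace = TRUE)
        tss <- ifelse(strand == "+", window_start + PROMOTER_UPSTREAM,
                      window_start + PROMOTER_DOWNSTREAM)
        ids <- idx0 + seq_len(k)
        rows[[ci]] <- data.frame(
          gene_symbol = sprintf("Gene%04d", ids),
          entrez_id = 100000L + ids,
          chrom = names(lens)[ci],
          tss = tss,
          strand = strand,
          window_start = window_start,
          window_end = window_start + width,
          stringsAsFactors = FALSE)
        idx0 <- idx0 + k
      }
      promoters <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      rownames(promoters) <- NULL
      promoters$cpg_density <- runif(nrow(promoters),
                                     config$cpg_density_range[1],
                                     config$cpg_density_range[2])
      cpg_rows <- lapply(seq_len(nrow(promoters)), function(i) {
        p <- promoters[i, ]
        n_cpg <- rpois(1, p$cpg_density * width / 100)
        if (n_cpg == 0) return(NULL)
        # dinucleotide starts need >=2 bp separation to be distinct CpGs
        pos <- sort(unique(floor(runif(n_cpg, p$window_start, p$window_end - 1))))
        pos <- pos[c(TRUE, diff(pos) >= 2)]
        data.frame(chrom = p$chrom, pos = pos, stringsAsFactors = FALSE)
      })
      cpg_rows <- cpg_rows[!vapply(cpg_rows, is.null, logical(1))]
      cpg <- if (length(cpg_rows)) do.call(rbind, cpg_rows) else
        data.frame(chrom = character(), pos = numeric())
      cpg <- cpg[order(cpg$chrom, cpg$pos), , drop = FALSE]
      rownames(cpg) <- NULL
    }
    model <- list(chromosomes = chromosomes, promoters = promoters,
                  cpg = cpg, config = config)
    class(model) <- "genome_model"
    validate_genome_model(model)
    model
  })
}

validate_genome_model <- function(model) {
  p <- model$promoters
  if (nrow(p)) {
    lens <- setNames(model$chromosomes$length, model$chromosomes$chrom)
    stopifnot(all(p$window_start >= 0),
              all(p$window_end <= lens[p$chrom]),
              all(p$tss >= 0 & p$tss < lens[p$chrom]))
  }
  if (nrow(model$cpg)) {
    by_chrom <- split(model$cpg$pos, model$cpg$chrom)
    stopifnot(all(vapply(by_chrom, function(x) all(diff(x) > 0), logical(1))))
  }
  invisible(model)
}

#' Plant ground-truth differentially methylated intervals
#'
#' Chooses `n` distinct promoters and places one spiked interval of width
#' `width_bp` centred in each promoter window.  The spike shifts the treatment
#' channel (Cy3) log2 intensity by `effect_m` with a random sign, so spiked
#' probes show M = Cy5 − Cy3 of the opposite sign.  Promoters are drawn from
#' those whose window CpG density is at least `min_cpg_density`, so planted
#' truths are compatible with the region-level CpG filter applied at calling
#' time; the default keeps the realized density of a called region above the
#' 1/100 bp reporting floor with high probability despite Poisson sampling of
#' CpG positions.
#'
#' @param genome a `genome_model`.
#' @param n number of DMRs to plant.
#' @param effect_m absolute log2 shift added to the treatment channel.
#' @param width_bp spike width in bp.
#' @param min_cpg_density minimum promoter CpG density (per 100 bp) eligible
#'   for spiking.
#' @param seed RNG seed.
#' @return data.frame (chrom, start, end, effect_m, sign, gene_symbol) — the
#'   truth table; `sign` is the sign of the induced M shift.
#' @export
spike_dmrs <- function(genome, n, effect_m = 1, width_bp = 800L,
                       min_cpg_density = 2, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), n >= 0, effect_m != 0,
            is.finite(effect_m), width_bp > 0)
  p <- genome$promoters
  eligible <- which(p$cpg_density >= min_cpg_density)
  if (n > length(eligible)) {
    stop(sprintf("requested %d spiked DMRs but only %d promoters have CpG density >= %.2f",
                 n, length(eligible), min_cpg_density))
  }
  with_seed(seed, {
    if (n == 0L) {
      return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                        effect_m = numeric(), sign = integer(),
                        gene_symbol = character(), stringsAsFactors = FALSE))
    }
    pick <- sort(sample(eligible, n))
    centre <- (p$window_start[pick] + p$window_end[pick]) / 2
    start <- floor(centre - width_bp / 2)
    eff <- abs(effect_m) * sample(c(-1, 1), n, replace = TRUE)
    out <- data.frame(chrom = p$chrom[pick],
                      start = start,
                      end = start + width_bp,
                      effect_m = eff,
                      sign = as.integer(-sign(eff)),  # M = Cy5 - Cy3
                      gene_symbol = p$gene_symbol[pick],
                      stringsAsFactors = FALSE)
    out[order(out$chrom, out$start), ]
  })
}
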