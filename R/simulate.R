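#' Simulation parameters for comparative two-channel hybridizations
#'
#' @param n_hybridizations number of comparative hybridizations (sub-arrays);
#'   the study design uses 3.
#' @param dye_bias either a function `(A, gc_fraction) -> offset` added to the
#'   Cy5 log2 intensity (an M offset), or a list with `gc_slope` and `a_slope`
#'   defining the default linear family
#'   `gc_slope * (gc_fraction - 0.5) + a_slope * (A - 10)`.  Use
#'   `dye_bias = NULL` for no bias.
#' @param noise_sd per-channel Gaussian noise sd in log2 units.
#' @param baseline_range per-promoter mean log2 intensity range; promoter
#'   means are drawn uniformly from it and probes inherit their promoter's
#'   mean.  MeDIP promoter-array intensities sit near 2^10-2^11; the default
#'   floor leaves headroom above the 9.5 reporting filter even for planted
#'   hypomethylation events, whose A drops by half the planted M effect.
#' @param probe_sd per-probe deviation (sd, log2) around the promoter mean,
#'   shared by both channels of a hybridization.
#' @param seed RNG seed (mandatory, recorded in the output).
#' @return list of class `array_sim_params`.
#' @export
array_sim_params <- function(n_hybridizations = 3L,
                             dye_bias = list(gc_slope = 0.6, a_slope = 0.15),
                             noise_sd = 0.2,
                             baseline_range = c(10.2, 11.6),
                             probe_sd = 0.3,
                             seed = 1L) {
  stopifnot(n_hybridizations >= 2, noise_sd >= 0, probe_sd >= 0,
            length(baseline_range) == 2, baseline_range[1] <= baseline_range[2])
  structure(list(n_hybridizations = as.integer(n_hybridizations),
                 dye_bias = dye_bias, noise_sd = noise_sd,
                 baseline_range = as.numeric(baseline_range),
                 probe_sd = probe_sd, seed = seed),
            class = "array_sim_params")
}

dye_bias_fun <- function(dye_bias) {
  if (is.null(dye_bias)) return(function(A, gc) rep(0, length(A)))
  if (is.function(dye_bias)) return(dye_bias)
  function(A, gc) dye_bias$gc_slope * (gc - 0.5) + dye_bias$a_slope * (A - 10)
}

#' Simulate comparative MeDIP hybridizations with planted DMRs
#'
#' For each hybridization and probe, both channels share a probe-level
#' baseline (promoter mean plus probe deviation); the control channel (Cy5)
#' additionally receives the GC/intensity-dependent dye-bias offset, the
#' treatment channel (Cy3) receives `effect_m` for probes overlapping a
#' spiked interval, and both receive independent Gaussian noise.  With zero
#' noise and no bias or spikes, Cy3 equals Cy5 exactly.
#'
#' @param design a `probe_design`.
#' @param dmrs truth table from [spike_dmrs()] (may have zero rows).
#' @param params an [array_sim_params()].
#' @return list of class `raw_array_set` with `cy3` and `cy5` matrices
#'   (probes x hybridizations, log2), the `design`, the `truth` table, a
#'   logical `spiked` flag per probe, and `params`.
#' @export
simulate_medip_arrays <- function(design, dmrs, params = array_sim_params()) {
  stopifnot(inherits(design, "probe_design"), inherits(params, "array_sim_params"))
  pr <- design$probes
  n <- nrow(pr)
  H <- params$n_hybridizations
  bias <- dye_bias_fun(params$dye_bias)
  spiked <- rep(FALSE, n)
  effect <- rep(0, n)
  if (nrow(dmrs)) {
    for (k in seq_len(nrow(dmrs))) {
      hit <- pr$chrom == dmrs$chrom[k] & pr$start < dmrs$end[k] & pr$end > dmrs$start[k]
      spiked <- spiked | hit
      effect[hit] <- dmrs$effect_m[k]
    }
  }
  with_seed(params$seed, {
    prom_mean <- runif(nrow(design$genome$promoters),
                       params$baseline_range[1], params$baseline_range[2])
    cy3 <- matrix(NA_real_, n, H)
    cy5 <- matrix(NA_real_, n, H)
    for (h in seq_len(H)) {
      base <- prom_mean[pr$promoter_index] +
        if (params$probe_sd > 0) rnorm(n, 0, params$probe_sd) else 0
      b <- bias(base, pr$gc_fraction)
      noise3 <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else 0
      noise5 <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else 0
      cy3[, h] <- base + effect + noise3
      cy5[, h] <- base + b + noise5
    }
    dimnames(cy3) <- dimnames(cy5) <-
      list(pr$probe_id, sprintf("hyb%d", seq_len(H)))
    structure(list(cy3 = cy3, cy5 = cy5, design = design, truth = dmrs,
                   spiked = spiked, params = params),
              class = "raw_array_set")
  })
}

#' Simulation parameters for the pooled expression matrix
#'
#' @param n_genes total genes.
#' @param n_de_genes planted differentially expressed genes.
#' @param fold_change_range range of planted fold changes (> 1); direction is
#'   random per gene.
#' @param n_per_group pooled samples per group (3 vs 3 in the study design).
#' @param noise_sd log2-scale noise sd applied to each sample's signal.
#' @param baseline_range unlogged baseline signal range; the default keeps
#'   planted mean differences above the 10-unit floor.
#' @param seed RNG seed.
#' @return list of class `expression_sim_params`.
#' @export
expression_sim_params <- function(n_genes = 1000L, n_de_genes = 50L,
                                  fold_change_range = c(1.5, 3),
                                  n_per_group = 3L, noise_sd = 0.1,
                                  baseline_range = c(50, 500), seed = 1L) {
  stopifnot(n_de_genes <= n_genes, all(fold_change_range > 1),
            n_per_group >= 2, noise_sd >= 0, all(baseline_range > 0))
  structure(list(n_genes = as.integer(n_genes),
                 n_de_genes = as.integer(n_de_genes),
                 fold_change_range = as.numeric(fold_change_range),
                 n_per_group = as.integer(n_per_group),
                 noise_sd = noise_sd,
                 baseline_range = as.numeric(baseline_range),
                 seed = seed),
            class = "expression_sim_params")
}

#' Simulate a pooled expression matrix with planted fold changes
#'
#' Produces unlogged signals for `n_genes` genes across treatment and control
#' pools.  Planted genes have a treatment/control mean ratio drawn from
#' `fold_change_range` in a random direction; noise is log-normal
#' (Gaussian on log2 signals).
#'
#' @param params an [expression_sim_params()].
#' @return list of class `expression_sim` with `matrix` (unlogged signals,
#'   genes x samples named T1..Tn, C1..Cn), `groups` (factor per column),
#'   `truth` (data.frame: gene, fold_change, direction), and `params`.
#' @export
simulate_expression_matrix <- function(params = expression_sim_params()) {
  stopifnot(inherits(params, "expression_sim_params"))
  with_seed(params$seed, {
    n <- params$n_genes
    k <- params$n_per_group
    genes <- sprintf("Gene%04d", seq_len(n))
    base <- runif(n, params$baseline_range[1], params$baseline_range[2])
    fold <- rep(1, n)
    de_idx <- if (params$n_de_genes > 0) sort(sample.int(n, params$n_de_genes)) else integer()
    if (length(de_idx)) {
      f <- runif(length(de_idx), params$fold_change_range[1], params$fold_change_range[2])
      dir <- sample(c(1, -1), length(de_idx), replace = TRUE)
      fold[de_idx] <- ifelse(dir > 0, f, 1 / f)
    }
    treat_mean <- base * fold
    noisy <- function(mu) {
      m <- matrix(rep(log2(mu), k), nrow = n)
      if (params$noise_sd > 0) m <- m + matrix(rnorm(n * k, 0, params$noise_sd), nrow = n)
      2^m
    }
    mat <- cbind(noisy(treat_mean), noisy(base))
    colnames(mat) <- c(sprintf("T%d", seq_len(k)), sprintf("C%d", seq_len(k)))
    rownames(mat) <- genes
    truth <- data.frame(gene = genes[de_idx],
                        fold_change = fold[de_idx],
                        direction = ifelse(fold[de_idx] >= 1, "up", "down"),
                        stringsAsFactors = FALSE)
    structure(list(matrix = mat,
                   groups = factor(rep(c("treatment", "control"), each = k)),
                   truth = truth, params = params),
              class = "expression_sim")
  })
}
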