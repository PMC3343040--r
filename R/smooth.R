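#' Sliding-window median smoothing of probe values
#'
#' Replaces each probe's value with the median of all (probe, array) values
#' whose probe midpoint lies within a `window_bp`-wide window centred on the
#' probe's midpoint (membership interval `[mid - w/2, mid + w/2)`), pooling
#' values across all supplied arrays.  If fewer than `min_probes` distinct
#' probes contribute to the window, no value is assigned (NA).
#'
#' @param values numeric matrix, probes x arrays (one column is allowed).
#' @param chrom,start,end probe coordinates (0-based half-open), sorted by
#'   (chrom, start); unsorted input is rejected.
#' @param window_bp total window width in bp.
#' @param min_probes minimum number of distinct probes (with at least one
#'   non-missing value) required in the window.
#' @return numeric vector of smoothed values, one per probe.
#' @export
window_median_smooth <- function(values, chrom, start, end,
                                 window_bp = 600, min_probes = 3L) {
  values <- as.matrix(values)
  n <- nrow(values)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n,
            window_bp > 0, min_probes >= 1)
  ord_ok <- !is.unsorted(order(chrom, start)) &&
    all(diff(order(chrom, start)) == 1)
  if (!ord_ok) stop("probes must be sorted by (chrom, start)")
  mid <- (start + end) / 2
  half <- window_bp / 2
  out <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- mid[idx]
    # membership: m[j] in [m[i] - half, m[i] + half)
    lo <- findInterval(m - half, m, left.open = TRUE) + 1L
    hi <- findInterval(m + half, m, left.open = TRUE)
    for (k in seq_along(idx)) {
      rows <- idx[lo[k]:hi[k]]
      v <- values[rows, , drop = FALSE]
      present <- rowSums(is.finite(v)) > 0
      if (sum(present) < min_probes) next
      out[idx[k]] <- median(v[is.finite(v)])
    }
  }
  out
}

#' Probe-level Z-scores against the empirical normal
#'
#' Standardizes each probe's smoothed M against a normal distribution scaled
#' to the mean and standard deviation (sample sd, n−1) of all non-missing
#' smoothed M values of the analysis, and assigns a two-sided normal tail
#' p-value.
#'
#' @param smoothed_m numeric vector of smoothed M values (NAs allowed).
#' @return data.frame with columns `Z` and `p` (NA where input is missing),
#'   with the fitted `mean` and `sd` as attributes.
#' @export
zscore_probes <- function(smoothed_m) {
  ok <- is.finite(smoothed_m)
  if (sum(ok) < 2) stop("need at least 2 non-missing smoothed values")
  mu <- mean(smoothed_m[ok])
  s <- sd(smoothed_m[ok])
  Z <- rep(NA_real_, length(smoothed_m))
  p <- rep(NA_real_, length(smoothed_m))
  if (s == 0) {
    warning("zero standard deviation of smoothed M; all p-values set to 1")
    Z[ok] <- 0
    p[ok] <- 1
  } else {
    Z[ok] <- (smoothed_m[ok] - mu) / s
    p[ok] <- 2 * pnorm(-abs(Z[ok]))
  }
  structure(data.frame(Z = Z, p = p), mean = mu, sd = s)
}

#' Enumerate paired comparative analyses
#'
#' The statistical analysis runs on pairs of comparative hybridizations; all
#' unordered pairs of the available hybridizations are analysed (3
#' hybridizations give the pairs {1,2}, {1,3}, {2,3}).
#'
#' @param n_hybridizations number of comparative hybridizations (>= 2).
#' @return list of integer vectors of length 2, named e.g. `"hyb1+hyb2"`.
#' @export
make_pairs <- function(n_hybridizations) {
  if (n_hybridizations < 2) stop("need at least 2 hybridizations to form pairs")
  cmb <- combn(n_hybridizations, 2, simplify = FALSE)
  names(cmb) <- vapply(cmb, function(p) sprintf("hyb%d+hyb%d", p[1], p[2]),
                       character(1))
  cmb
}

#' Smoothed per-pair probe profiles with Z statistics
#'
#' For each pair of hybridizations, pools the pair's normalized M (and A)
#' values, applies 600 bp window-median smoothing, and computes probe Z-scores
#' and p-values against the pair's empirical normal.
#'
#' @param ma a normalized `ma_array`.
#' @param window_bp smoothing window width in bp.
#' @param min_probes minimum distinct probes per window.
#' @param smooth_scope `"pair"` (default) smooths over the two arrays of each
#'   pair; `"global"` smooths once across all arrays and reuses the result in
#'   every pair.
#' @return named list of data.frames (one per pair): probe_id, chrom, start,
#'   end, smoothed_M, smoothed_A, Z, p; each has attributes `pair_id`,
#'   `mean`, `sd`.
#' @export
pair_profiles <- function(ma, window_bp = 600, min_probes = 3L,
                          smooth_scope = c("pair", "global")) {
  stopifnot(inherits(ma, "ma_array"))
  smooth_scope <- match.arg(smooth_scope)
  pr <- ma$design$probes
  pairs <- make_pairs(ncol(ma$M))
  global_m <- global_a <- NULL
  if (smooth_scope == "global") {
    global_m <- window_median_smooth(ma$M, pr$chrom, pr$start, pr$end,
                                     window_bp, min_probes)
    global_a <- window_median_smooth(ma$A, pr$chrom, pr$start, pr$end,
                                     window_bp, min_probes)
  }
  lapply(setNames(names(pairs), names(pairs)), function(id) {
    cols <- pairs[[id]]
    if (smooth_scope == "pair") {
      sm <- window_median_smooth(ma$M[, cols, drop = FALSE], pr$chrom,
                                 pr$start, pr$end, window_bp, min_probes)
      sa <- window_median_smooth(ma$A[, cols, drop = FALSE], pr$chrom,
                                 pr$start, pr$end, window_bp, min_probes)
    } else {
      sm <- global_m
      sa <- global_a
    }
    zp <- zscore_probes(sm)
    out <- data.frame(probe_id = pr$probe_id, chrom = pr$chrom,
                      start = pr$start, end = pr$end,
                      smoothed_M = sm, smoothed_A = sa,
                      Z = zp$Z, p = zp$p, stringsAsFactors = FALSE)
    attr(out, "pair_id") <- id
    attr(out, "mean") <- attr(zp, "mean")
    attr(out, "sd") <- attr(zp, "sd")
    out
  })
}
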