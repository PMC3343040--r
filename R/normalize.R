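#' Convert a raw two-channel array set to M/A values
#'
#' M = Cy5 − Cy3 and A = (Cy5 + Cy3) / 2 element-wise on log2 intensities,
#' so positive M means higher signal in the control (Cy5) channel.  Probes
#' with a non-finite value in either channel are masked (NA in both M and A)
#' but keep their design row.
#'
#' @param raw a `raw_array_set`.
#' @return list of class `ma_array` with `M` and `A` matrices (probes x
#'   hybridizations), `gc_bin` (assigned by [gc_binned_loess()]), `design`,
#'   and an `audit` list.
#' @export
to_ma <- function(raw) {
  stopifnot(inherits(raw, "raw_array_set"))
  bad <- !is.finite(raw$cy3) | !is.finite(raw$cy5)
  M <- raw$cy5 - raw$cy3
  A <- (raw$cy5 + raw$cy3) / 2
  M[bad] <- NA_real_
  A[bad] <- NA_real_
  structure(list(M = M, A = A, gc_bin = NULL, design = raw$design,
                 audit = list(masked = sum(bad))),
            class = "ma_array")
}

# Quantile-based GC bins over gc_fraction; merges bins smaller than min_size
# into their nearest neighbour.
assign_gc_bins <- function(gc_fraction, n_bins = 5L, min_size = 50L) {
  qs <- quantile(gc_fraction, probs = seq(0, 1, length.out = n_bins + 1),
                 na.rm = TRUE, names = FALSE)
  qs <- unique(qs)
  if (length(qs) < 2) return(factor(rep(1L, length(gc_fraction))))
  bin <- cut(gc_fraction, breaks = qs, include.lowest = TRUE, labels = FALSE)
  # merge undersized bins into the nearest (by bin index) larger neighbour
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < min_size]
    if (!length(small) || length(tab) == 1) break
    b <- as.integer(small[1])
    others <- as.integer(names(tab)[names(tab) != small[1]])
    target <- others[which.min(abs(others - b))]
    warning(sprintf("GC bin %d has fewer than %d probes; merged into bin %d",
                    b, min_size, target), call. = FALSE)
    bin[bin == b] <- target
  }
  factor(bin)
}

#' GC-binned loess normalization of M within each array
#'
#' Within each hybridization, probes are grouped into GC-content bins
#' (quantiles of GC fraction) and, separately per bin, the loess trend of M
#' on A is subtracted from M, so each GC group receives its own
#' intensity-dependent dye-bias correction.  A is left unchanged.
#'
#' @param ma an `ma_array`.
#' @param n_bins number of GC bins (quantile-based).
#' @param span loess span.
#' @param min_bin_size bins with fewer probes are merged into the nearest bin.
#' @return the `ma_array` with normalized `M`, `gc_bin` filled in, and loess
#'   settings appended to the audit.
#' @export
gc_binned_loess <- function(ma, n_bins = 5L, span = 0.4, min_bin_size = 50L) {
  stopifnot(inherits(ma, "ma_array"), n_bins >= 1, span > 0)
  gc <- ma$design$probes$gc_fraction
  bin <- assign_gc_bins(gc, n_bins, min_bin_size)
  M <- ma$M
  for (h in seq_len(ncol(M))) {
    for (b in levels(bin)) {
      idx <- which(bin == b)
      ok <- idx[is.finite(M[idx, h]) & is.finite(ma$A[idx, h])]
      if (length(ok) < 2) next
      fit <- limma::loessFit(M[ok, h], ma$A[ok, h], span = span)
      M[ok, h] <- M[ok, h] - fit$fitted
    }
  }
  ma$M <- M
  ma$gc_bin <- bin
  ma$audit$loess <- list(n_bins = nlevels(bin), span = span,
                         bin_sizes = as.integer(table(bin)))
  ma
}

#' Quantile-normalize A values across hybridizations
#'
#' Each array's sorted A values are replaced by the rank-wise mean of the
#' sorted A values across all arrays (ties share the mean of their ranks'
#' values); M is untouched.  Probes masked in an array are excluded from that
#' array's ranking and restored as missing.  The A-only reading keeps the
#' loess-normalized M intact while making intensity distributions comparable
#' across arrays.
#'
#' @param ma an `ma_array` spanning at least 2 hybridizations (a single array
#'   is returned unchanged with a warning).
#' @return the `ma_array` with normalized `A`.
#' @export
quantile_normalize_A <- function(ma) {
  stopifnot(inherits(ma, "ma_array"))
  A <- ma$A
  if (ncol(A) < 2) {
    warning("quantile normalization with a single array is the identity")
    return(ma)
  }
  ma$A <- quantile_normalize_matrix(A)
  ma$audit$aquantile <- TRUE
  ma
}

# Rank-wise-mean quantile normalization with NA handling: each column's
# non-missing values are mapped onto the mean quantile function via their
# fractional ranks; missing entries stay missing.
quantile_normalize_matrix <- function(A) {
  n <- nrow(A)
  # mean quantile function on a common grid of n probabilities
  grid <- if (n == 1) 0.5 else seq(0, 1, length.out = n)
  cols_q <- vapply(seq_len(ncol(A)), function(j) {
    x <- A[, j]
    ok <- is.finite(x)
    quantile(x[ok], probs = grid, names = FALSE, type = 7)
  }, numeric(n))
  target <- rowMeans(cols_q)
  out <- A
  for (j in seq_len(ncol(A))) {
    x <- A[, j]
    ok <- which(is.finite(x))
    m <- length(ok)
    if (!m) next
    r <- rank(x[ok], ties.method = "average")
    p <- if (m == 1) 0.5 else (r - 1) / (m - 1)
    # interpolate the mean quantile function at this column's rank quantiles
    out[ok, j] <- stats::approx(grid, target, xout = p, rule = 2)$y
  }
  out
}
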