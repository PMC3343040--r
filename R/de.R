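#' Cutoff-based differential-expression filter
#'
#' Applies the three-criterion cutoff to an unlogged expression matrix with
#' two groups: treatment/control signal ratio above `ratio_threshold` in
#' magnitude (strictly, in either direction), absolute unlogged mean
#' difference above `diff_threshold` (strictly), and a two-sided Welch t-test
#' on log2 signals with p below `p_threshold`.  Genes with zero variance in
#' both groups get p = 1.  An optional batch label mean-centres log2 signals
#' within batch before testing.
#'
#' @param matrix unlogged signal matrix, genes x samples (rownames = genes).
#' @param groups factor/character per column with exactly two levels,
#'   `"treatment"` and `"control"`.
#' @param ratio_threshold fold-change cutoff (default 1.20, strict).
#' @param diff_threshold unlogged mean-difference cutoff (default 10, strict,
#'   on the absolute difference).
#' @param p_threshold t-test cutoff (default 0.05, strict).
#' @param batch optional batch label per column; log2 signals are centred
#'   within batch before the t-test when supplied.
#' @return data.frame per gene: gene, ratio (treatment/control), mean_difference
#'   (treatment − control, unlogged), t_p, direction ("up"/"down"), and the
#'   three criterion flags plus `passes`.
#' @export
de_filter <- function(matrix, groups, ratio_threshold = 1.20,
                      diff_threshold = 10, p_threshold = 0.05, batch = NULL) {
  stopifnot(is.matrix(matrix), all(matrix > 0), ncol(matrix) == length(groups))
  groups <- as.character(groups)
  stopifnot(setequal(unique(groups), c("treatment", "control")))
  ti <- which(groups == "treatment")
  ci <- which(groups == "control")
  stopifnot(length(ti) >= 2, length(ci) >= 2)
  lg <- log2(matrix)
  if (!is.null(batch)) {
    stopifnot(length(batch) == ncol(matrix))
    for (b in unique(batch)) {
      cols <- which(batch == b)
      lg[, cols] <- lg[, cols] - rowMeans(lg[, cols, drop = FALSE]) +
        rowMeans(lg)
    }
  }
  tm <- rowMeans(matrix[, ti, drop = FALSE])
  cm <- rowMeans(matrix[, ci, drop = FALSE])
  ratio <- tm / cm
  diff <- tm - cm
  t_p <- vapply(seq_len(nrow(matrix)), function(i) {
    x <- lg[i, ti]; y <- lg[i, ci]
    if (sd(x) == 0 && sd(y) == 0) return(1)
    t.test(x, y)$p.value
  }, numeric(1))
  pass_ratio <- ratio > ratio_threshold | ratio < 1 / ratio_threshold
  pass_diff <- abs(diff) > diff_threshold
  pass_p <- t_p < p_threshold
  data.frame(gene = rownames(matrix) %||% as.character(seq_len(nrow(matrix))),
             ratio = ratio, mean_difference = diff, t_p = t_p,
             direction = ifelse(ratio >= 1, "up", "down"),
             pass_ratio = pass_ratio, pass_diff = pass_diff, pass_p = pass_p,
             passes = pass_ratio & pass_diff & pass_p,
             stringsAsFactors = FALSE, row.names = NULL)
}
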