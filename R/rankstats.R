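RANK_STATISTICS <- c("auc", "mncp", "pearson", "spearman")

check_scores <- function(positives, negatives) {
  if (!length(positives) || !length(negatives))
    stop("both score classes must be nonempty")
  if (!all(is.finite(positives)) || !all(is.finite(negatives)))
    stop("scores must be finite")
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (positive, negative) score pairs where
#' the positive outscores the negative, counting ties as half. Computed from
#' midranks, so it is invariant under strictly monotone transforms and
#' symmetric in the sense `auc(p, n) + auc(n, p) = 1`.
#'
#' @param positives numeric scores of the positive class.
#' @param negatives numeric scores of the negative class.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(positives, negatives) {
  check_scores(positives, negatives)
  np <- length(positives); nn <- length(negatives)
  r <- rank(c(positives, negatives))  # midranks for ties
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Mean normalized conditional probability (MNCP)
#'
#' Rank-based statistic that emphasizes true positives: rank all N scores in
#' descending order (midranks for ties); for the i-th best positive with
#' overall rank r_i, the normalized conditional probability is
#' `(i / n_pos) / (r_i / N)`, and MNCP is the mean over positives. A random
#' ranking gives ~1; a perfect ranking with n_pos = n_neg gives 2.
#'
#' @inheritParams auc
#' @return A positive real.
#' @export
mncp <- function(positives, negatives) {
  check_scores(positives, negatives)
  np <- length(positives)
  N <- np + length(negatives)
  r_desc <- N + 1 - rank(c(positives, negatives))   # descending midranks
  r_pos <- sort(r_desc[seq_len(np)])                # i-th best positive
  mean((seq_len(np) / np) / (r_pos / N))
}

#' Pearson and Spearman correlation of scores
#'
#' Thin wrappers over [stats::cor] that reject degenerate input instead of
#' silently returning `NA`: used to correlate motif scores with peak signal
#' (ChIP-seq) or probe intensity (PBM).
#'
#' @param x,y equal-length numeric vectors, length >= 3, each with nonzero
#'   variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  check_cor_input(x, y)
  stats::cor(x, y, method = "pearson")
}

#' @rdname pearson_cor
#' @export
spearman_cor <- function(x, y) {
  check_cor_input(x, y)
  stats::cor(x, y, method = "spearman")
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
}

#' Compare two score distributions (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test between two score
#' vectors, e.g. AUCs obtained under two benchmark configurations. Uses the
#' exact distribution for small tie-free samples and the normal approximation
#' with tie correction otherwise; fully tied inputs give p = 1.
#'
#' @param a,b numeric score vectors.
#' @return List with `p_value`, `statistic` (Mann-Whitney U of `a` over `b`)
#'   and `direction` (`"a>b"`, `"b>a"` or `"tie"` by rank-sum).
#' @export
compare_configs <- function(a, b) {
  check_scores(a, b)
  u <- auc(a, b) * length(a) * length(b)
  if (length(unique(c(a, b))) == 1L) {
    p <- 1
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                             correct = TRUE)$p.value)
    if (!is.finite(p)) p <- 1
  }
  mid <- length(a) * length(b) / 2
  list(p_value = min(p, 1), statistic = u,
       direction = if (u > mid) "a>b" else if (u < mid) "b>a" else "tie")
}

#' Normalize values by their maximum
#'
#' @param values numeric vector with positive maximum.
#' @return `values / max(values)`; the maximum of the output is 1.
#' @export
normalize_by_max <- function(values) {
  if (!length(values) || !all(is.finite(values)))
    stop("values must be nonempty and finite")
  m <- max(values)
  if (m <= 0) stop("maximum must be positive, got ", m)
  values / m
}

#' ROC curve points
#'
#' False/true positive rates at every distinct score threshold, suitable for
#' TSV export and plotting.
#'
#' @inheritParams auc
#' @return data.frame with columns `fpr`, `tpr`, monotone nondecreasing.
#' @export
roc_points <- function(positives, negatives) {
  check_scores(positives, negatives)
  th <- sort(unique(c(positives, negatives)), decreasing = TRUE)
  data.frame(
    fpr = c(0, vapply(th, function(t) mean(negatives >= t), numeric(1))),
    tpr = c(0, vapply(th, function(t) mean(positives >= t), numeric(1))))
}
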