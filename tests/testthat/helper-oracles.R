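# Independent brute-force oracles. These deliberately avoid the package's
# scanning internals: every window is enumerated explicitly and scored by a
# direct per-position product/sum over the PWM columns.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# list of character windows, one per start position
oracle_window_chars <- function(sequence, k, strand) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  wins <- lapply(seq_len(L - k + 1L), function(t) chars[t:(t + k - 1L)])
  if (strand == "both") {
    rchars <- strsplit(oracle_revcomp(sequence), "")[[1]]
    wins <- c(wins, lapply(seq_len(L - k + 1L),
                           function(t) rchars[t:(t + k - 1L)]))
  }
  wins
}

# window probability: product of per-base PWM probabilities, N -> 0.25
oracle_all_probs <- function(mat, sequence, strand) {
  k <- ncol(mat)
  vapply(oracle_window_chars(sequence, k, strand), function(b) {
    p <- rep(0.25, k)
    real <- which(b != "N")
    p[real] <- mat[cbind(match(b[real], rownames(mat)), real)]
    prod(p)
  }, numeric(1))
}

oracle_gomer_from_probs <- function(p) {
  direct <- 1 - prod(1 - p)
  # avoid the oracle's own cancellation when the complement product is ~1
  if (direct > 1e-3) direct else -expm1(sum(log1p(-pmin(p, 1))))
}

oracle_gomer <- function(mat, sequence, strand)
  oracle_gomer_from_probs(oracle_all_probs(mat, sequence, strand))

oracle_sumoc <- function(mat, sequence, strand)
  sum(oracle_all_probs(mat, sequence, strand))

oracle_maxoc <- function(mat, sequence, strand)
  max(oracle_all_probs(mat, sequence, strand))

oracle_ama <- function(mat, sequence, strand)
  mean(oracle_all_probs(mat, sequence, strand))

oracle_energy <- function(mat, sequence, strand, mu = 0, pseudo = 1e-3) {
  ps <- pmax(mat, pseudo)
  k <- ncol(mat)
  cmax <- apply(ps, 2, max)
  energies <- vapply(oracle_window_chars(sequence, k, strand), function(b) {
    if (any(b == "N")) return(NA_real_)
    sum(-log(ps[cbind(match(b, rownames(ps)), seq_len(k))] / cmax))
  }, numeric(1))
  energies <- energies[!is.na(energies)]
  if (!length(energies)) return(NA_real_)
  1 / (1 + exp(min(energies) - mu))
}

oracle_logodds_windows <- function(mat, sequence, strand,
                                   background = rep(0.25, 4), pseudo = 1e-3) {
  ps <- pmax(mat, pseudo)
  k <- ncol(mat)
  names(background) <- c("A", "C", "G", "T")
  vapply(oracle_window_chars(sequence, k, strand), function(b) {
    keep <- which(b != "N")
    if (!length(keep)) return(0)
    sum(log2(ps[cbind(match(b[keep], rownames(ps)), keep)] /
               background[b[keep]]))
  }, numeric(1))
}

oracle_logodds <- function(mat, sequence, mode, strand,
                           background = rep(0.25, 4), pseudo = 1e-3) {
  s <- oracle_logodds_windows(mat, sequence, strand, background, pseudo)
  if (mode == "sum") sum(s) else max(s)
}

# pairwise-counting AUC
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# exact two-sided Wilcoxon rank-sum p-value by exhaustive label enumeration,
# replicating the two-sided doubling rule
oracle_wilcox_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  combos <- utils::combn(length(pooled), na)
  stat <- apply(combos, 2, function(idx) sum(r[idx])) - na * (na + 1) / 2
  obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  p_le <- mean(stat <= obs)
  p_ge <- mean(stat >= obs)
  min(1, 2 * min(p_le, p_ge))
}

oracle_dinuc_counts <- function(s) {
  b <- strsplit(s, "")[[1]]
  if (length(b) < 2) return(table(character(0)))
  table(paste0(b[-length(b)], b[-1]))
}

# random test-case generators
random_pwm <- function(k, name = "rand") {
  m <- matrix(stats::rgamma(4 * k, shape = 0.8) + 1e-9, 4, k)
  m <- sweep(m, 2, colSums(m), "/")
  pwm(m, name = name)
}

random_seq <- function(L, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(rep(0.235, 4), 0.06) else rep(0.25, 4)
  paste(sample(alpha, L, replace = TRUE, prob = prob), collapse = "")
}

pwm_mat <- function(motif) {
  m <- unclass(motif)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

uniform_pwm <- function(k, name = "uniform") pwm(matrix(0.25, 4, k), name = name)

# PWM with one deterministic base per column following a consensus string
consensus_pwm <- function(consensus, name = consensus) {
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(0, 4, length(idx))
  m[cbind(idx, seq_along(idx))] <- 1
  pwm(m, name = name)
}
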