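SCORING_FUNCTIONS <- c("gomer", "sumoc", "maxoc", "ama", "energy",
                       "sumlog", "maxlog")

# Base encoding used by the scanners: A=1 C=2 G=3 T=4 N=5.
encode_dna <- local({
  map <- integer(256)
  map[utf8ToInt("A")] <- 1L; map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L; map[utf8ToInt("T")] <- 4L
  map[utf8ToInt("N")] <- 5L
  function(sequence) {
    enc <- map[utf8ToInt(toupper(sequence))]
    if (any(enc == 0L))
      stop("invalid character in sequence (only A, C, G, T, N allowed)")
    enc
  }
})

# Reverse complement in encoded space (A<->T, C<->G, N fixed).
revcomp_enc <- function(enc) {
  rc <- 5L - enc
  rc[enc == 5L] <- 5L
  rev(rc)
}

# 5 x k per-base lookup tables for one motif: log probability (N row =
# log 0.25), energy (N row = NA so windows containing N are skipped) and
# log2-odds (N row = 0, neutral). Zero probabilities are floored at the
# pseudo-probability before any log; nonzero entries are untouched.
motif_lookups <- function(motif, background = rep(0.25, 4), mu = 0,
                          pseudo = 1e-3) {
  p <- unclass(motif)
  k <- ncol(p)
  ps <- pmax(p, pseudo)
  logp <- rbind(log(p), rep(log(0.25), k))          # exact probs for Eq. products
  eps <- -log(sweep(ps, 2, apply(ps, 2, max), "/")) # energy, consensus = 0
  energy <- rbind(eps, rep(NA_real_, k))
  lodds <- rbind(log2(ps) - log2(background), rep(0, k))
  list(k = k, logp = logp, energy = energy, lodds = lodds, mu = mu)
}

# Per-window column sums of a 5 x k lookup over all L-k+1 windows of an
# encoded sequence: returns a numeric vector of window scores.
scan_windows <- function(enc, lookup, k) {
  L <- length(enc)
  nw <- L - k + 1L
  pos <- rep(seq_len(nw), k) + rep(seq_len(k) - 1L, each = nw)
  flat <- lookup[cbind(enc[pos], rep(seq_len(k), each = nw))]
  .rowSums(flat, nw, k)
}

check_scan <- function(L, k) {
  if (k > L)
    stop("sequence (length ", L, ") shorter than motif (length ", k, ")")
}

# Window probabilities P(window | PWM) on the requested strand(s).
window_probs <- function(enc, lk, strand) {
  wp <- exp(scan_windows(enc, lk$logp, lk$k))
  if (strand == "both")
    wp <- c(wp, exp(scan_windows(revcomp_enc(enc), lk$logp, lk$k)))
  pmin(wp, 1)
}

#' Occupancy probability of a single window
#'
#' The probability that the motif generates the window: the product over
#' positions of the PWM probability of the observed base. `N` contributes the
#' background probability 0.25.
#'
#' @param motif a [pwm].
#' @param window DNA string whose length equals the motif length.
#' @return A probability in \[0, 1\].
#' @export
window_probability <- function(motif, window) {
  stopifnot(is_pwm(motif))
  enc <- encode_dna(window)
  if (length(enc) != motif_length(motif))
    stop("window length ", length(enc), " != motif length ",
         motif_length(motif))
  lk <- motif_lookups(motif)
  min(exp(scan_windows(enc, lk$logp, lk$k)), 1)
}

#' GOMER sequence score
#'
#' Probability that the factor is bound to at least one window of the
#' sequence, assuming windows bind independently:
#' `1 - prod over windows of (1 - P(window | PWM))`, over all L - k + 1
#' windows (and their reverse complements when `strand = "both"`). Computed
#' in log space as `sum(log1p(-P))`, with an exact early return of 1 when any
#' window has probability 1.
#'
#' @inheritParams window_probability
#' @param sequence DNA string of length >= the motif length.
#' @param strand `"both"` (default: scan forward and reverse-complement
#'   windows) or `"single"`.
#' @return A probability in \[0, 1\].
#' @export
gomer_score <- function(motif, sequence, strand = c("both", "single")) {
  strand <- match.arg(strand)
  stopifnot(is_pwm(motif))
  enc <- encode_dna(sequence)
  check_scan(length(enc), motif_length(motif))
  gomer_from_probs(window_probs(enc, motif_lookups(motif), strand))
}

gomer_from_probs <- function(wp) {
  if (any(wp >= 1)) return(1)
  -expm1(sum(log1p(-wp)))
}

#' Occupancy scores of a sequence
#'
#' Aggregate the window occupancy probabilities of all scanned windows:
#' `sum_occupancy()` sums them, `max_occupancy()` takes the maximum and
#' `ama_score()` (average motif affinity) their mean.
#'
#' @inheritParams gomer_score
#' @return A nonnegative real (`sum_occupancy`) or a probability
#'   (`max_occupancy`, `ama_score`).
#' @export
sum_occupancy <- function(motif, sequence, strand = c("both", "single")) {
  strand <- match.arg(strand)
  stopifnot(is_pwm(motif))
  enc <- encode_dna(sequence)
  check_scan(length(enc), motif_length(motif))
  sum(window_probs(enc, motif_lookups(motif), strand))
}

#' @rdname sum_occupancy
#' @export
max_occupancy <- function(motif, sequence, strand = c("both", "single")) {
  strand <- match.arg(strand)
  stopifnot(is_pwm(motif))
  enc <- encode_dna(sequence)
  check_scan(length(enc), motif_length(motif))
  max(window_probs(enc, motif_lookups(motif), strand))
}

#' @rdname sum_occupancy
#' @export
ama_score <- function(motif, sequence, strand = c("both", "single")) {
  strand <- match.arg(strand)
  stopifnot(is_pwm(motif))
  enc <- encode_dna(sequence)
  check_scan(length(enc), motif_length(motif))
  mean(window_probs(enc, motif_lookups(motif), strand))
}

#' Convert a PWM to a binding-energy matrix
#'
#' Per-position energy contributions in the Boltzmann binding model:
#' `epsilon(b, t) = -ln(theta_t[b] / max_b' theta_t[b'])` after flooring zero
#' probabilities at the pseudo-probability `pseudo`. The consensus base of
#' every column has energy 0 and all energies are nonnegative; lower window
#' energy means higher predicted affinity.
#'
#' @inheritParams window_probability
#' @param mu chemical potential (dimensionless energy units, default 0).
#' @param pseudo pseudo-probability used to smooth zeros (default 1e-3).
#' @return An object of class `energy_matrix`: 4 x L matrix `epsilon` plus
#'   field `mu`.
#' @export
pwm_to_energy <- function(motif, mu = 0, pseudo = 1e-3) {
  stopifnot(is_pwm(motif))
  p <- unclass(motif)
  ps <- pmax(p, pseudo)
  eps <- -log(sweep(ps, 2, apply(ps, 2, max), "/"))
  structure(list(epsilon = eps, mu = mu, name = motif_name(motif)),
            class = "energy_matrix")
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("energy matrix '%s', length %d, mu = %g\n", x$name,
              ncol(x$epsilon), x$mu))
  print(x$epsilon)
  invisible(x)
}

#' Binding-energy sequence score
#'
#' Scans all windows, takes the minimum window energy E* (sum over positions
#' of `epsilon(base, position)`) and returns the Boltzmann-form binding
#' probability `1 / (1 + exp(E* - mu))`. Higher values mean higher predicted
#' affinity. Windows containing `N` are skipped; a sequence whose every
#' window contains `N` scores `NA`.
#'
#' @inheritParams gomer_score
#' @inheritParams pwm_to_energy
#' @return A probability in (0, 1), or `NA` if no window is scorable.
#' @export
energy_score <- function(motif, sequence, mu = 0,
                         strand = c("both", "single"), pseudo = 1e-3) {
  strand <- match.arg(strand)
  stopifnot(is_pwm(motif))
  enc <- encode_dna(sequence)
  check_scan(length(enc), motif_length(motif))
  lk <- motif_lookups(motif, mu = mu, pseudo = pseudo)
  e <- scan_windows(enc, lk$energy, lk$k)
  if (strand == "both")
    e <- c(e, scan_windows(revcomp_enc(enc), lk$energy, lk$k))
  energy_from_windows(e, mu)
}

energy_from_windows <- function(e, mu) {
  e <- e[!is.na(e)]
  if (!length(e)) return(NA_real_)
  1 / (1 + exp(min(e) - mu))
}

#' Log-odds sequence score
#'
#' Per-window score: sum over positions of `log2(theta_t[b] / p_b)` against
#' background probabilities `p` (uniform 0.25 by default), with zero PWM
#' entries floored at the pseudo-probability. The sequence score is
#' the sum over all scanned windows (`mode = "sum"`) or the maximum
#' (`mode = "max"`). `N` positions contribute 0.
#'
#' @inheritParams gomer_score
#' @param background 4 background probabilities (A, C, G, T).
#' @param mode `"sum"` or `"max"` aggregation over windows.
#' @param pseudo pseudo-probability used to smooth zeros.
#' @return A real score (bits).
#' @export
log_odds_score <- function(motif, sequence, background = rep(0.25, 4),
                           mode = c("sum", "max"),
                           strand = c("both", "single"), pseudo = 1e-3) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  stopifnot(is_pwm(motif), length(background) == 4, all(background > 0))
  enc <- encode_dna(sequence)
  check_scan(length(enc), motif_length(motif))
  lk <- motif_lookups(motif, background = background, pseudo = pseudo)
  s <- scan_windows(enc, lk$lodds, lk$k)
  if (strand == "both")
    s <- c(s, scan_windows(revcomp_enc(enc), lk$lodds, lk$k))
  if (mode == "sum") sum(s) else max(s)
}

# All requested scoring functions for one motif over a list of encoded
# sequences, sharing the window scans. Returns a length(enc_list) x
# length(functions) matrix.
score_matrix <- function(motif, enc_list, functions, strand = "both",
                         background = rep(0.25, 4), mu = 0, pseudo = 1e-3) {
  bad <- setdiff(functions, SCORING_FUNCTIONS)
  if (length(bad))
    stop("unknown scoring function(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(SCORING_FUNCTIONS, collapse = ", "))
  lk <- motif_lookups(motif, background = background, mu = mu, pseudo = pseudo)
  need_wp <- any(functions %in% c("gomer", "sumoc", "maxoc", "ama"))
  need_en <- "energy" %in% functions
  need_lo <- any(functions %in% c("sumlog", "maxlog"))
  out <- matrix(NA_real_, length(enc_list), length(functions),
                dimnames = list(NULL, functions))
  for (i in seq_along(enc_list)) {
    enc <- enc_list[[i]]
    check_scan(length(enc), lk$k)
    renc <- if (strand == "both") revcomp_enc(enc)
    if (need_wp) {
      wp <- pmin(exp(scan_windows(enc, lk$logp, lk$k)), 1)
      if (strand == "both")
        wp <- c(wp, pmin(exp(scan_windows(renc, lk$logp, lk$k)), 1))
      if ("gomer" %in% functions) out[i, "gomer"] <- gomer_from_probs(wp)
      if ("sumoc" %in% functions) out[i, "sumoc"] <- sum(wp)
      if ("maxoc" %in% functions) out[i, "maxoc"] <- max(wp)
      if ("ama" %in% functions) out[i, "ama"] <- mean(wp)
    }
    if (need_en) {
      e <- scan_windows(enc, lk$energy, lk$k)
      if (strand == "both") e <- c(e, scan_windows(renc, lk$energy, lk$k))
      out[i, "energy"] <- energy_from_windows(e, mu)
    }
    if (need_lo) {
      s <- scan_windows(enc, lk$lodds, lk$k)
      if (strand == "both") s <- c(s, scan_windows(renc, lk$lodds, lk$k))
      if ("sumlog" %in% functions) out[i, "sumlog"] <- sum(s)
      if ("maxlog" %in% functions) out[i, "maxlog"] <- max(s)
    }
  }
  out
}

#' Score a sequence set with a scoring function
#'
#' Applies one scoring function to every sequence of a set for every motif.
#' Motifs longer than the set width are skipped with a warning.
#'
#' @param motifs a [pwm] or list of [pwm] objects.
#' @param sequences a [sequence_set].
#' @param fun scoring function name: one of `"gomer"`, `"sumoc"`, `"maxoc"`,
#'   `"ama"`, `"energy"`, `"sumlog"`, `"maxlog"`.
#' @inheritParams gomer_score
#' @inheritParams log_odds_score
#' @inheritParams pwm_to_energy
#' @return A list of `score_table` data.frames (columns `motif`, `fun`,
#'   `sequence_id`, `score`), one per retained motif, scores in sequence
#'   order.
#' @export
score_set <- function(motifs, sequences, fun,
                      strand = c("both", "single"),
                      background = rep(0.25, 4), mu = 0, pseudo = 1e-3) {
  strand <- match.arg(strand)
  if (is_pwm(motifs)) motifs <- list(motifs)
  if (!fun %in% SCORING_FUNCTIONS)
    stop("unknown scoring function '", fun, "'; valid names: ",
         paste(SCORING_FUNCTIONS, collapse = ", "))
  stopifnot(inherits(sequences, "sequence_set"))
  keep <- vapply(motifs, motif_length, integer(1)) <= sequences$width
  if (!all(keep))
    warning("motif(s) longer than sequence width skipped: ",
            paste(vapply(motifs[!keep], motif_name, character(1)),
                  collapse = ", "))
  enc_list <- lapply(sequences$seq, encode_dna)
  lapply(motifs[keep], function(m) {
    sm <- score_matrix(m, enc_list, fun, strand = strand,
                       background = background, mu = mu, pseudo = pseudo)
    structure(data.frame(motif = motif_name(m), fun = fun,
                         sequence_id = sequences$id, score = sm[, fun],
                         stringsAsFactors = FALSE, row.names = NULL),
              class = c("score_table", "data.frame"))
  })
}

#' Write score tables as TSV
#'
#' @param tables list of `score_table` data.frames from [score_set].
#' @param path output path.
#' @export
write_score_tables <- function(tables, path) {
  utils::write.table(do.call(rbind, tables), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
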