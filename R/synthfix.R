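#' Specification for a synthetic benchmark fixture
#'
#' Defines a self-contained study: an i.i.d. background genome, ChIP-seq-like
#' peaks with a known motif implanted at a known rate, decoy motifs standing
#' in for competing database entries, and PBM-like probe intensities. The
#' defaults describe the reference benchmark the package is validated on:
#' 500 peaks, 100 bp windows, 90% of positives carrying a true site from a
#' 10 bp, ~12-bit motif, 9 decoys, matched downstream negatives 500 bp away.
#'
#' @param seed integer seed; every derived artifact is deterministic in it.
#' @param genome_length total genome length in bp.
#' @param n_chrom number of chromosomes (length split evenly).
#' @param masked_fraction fraction of genome soft-masked (lowercase) in
#'   random intervals.
#' @param base_comp background base probabilities (A, C, G, T); 0-order
#'   i.i.d. so downstream and dinucleotide-shuffled negatives have identical
#'   expected composition.
#' @param n_peaks number of synthetic peaks.
#' @param peak_width called-peak width in bp.
#' @param window_width positive-window width in bp (sites are implanted
#'   inside the central window).
#' @param offset downstream-negative gap in bp.
#' @param site_rate probability a positive window carries a true site.
#' @param motif the true [pwm] (default [default_true_motif]).
#' @param n_decoys number of decoy motifs.
#' @param decoy_magnitude Dirichlet perturbation magnitude for decoys.
#' @param pbm_noise_sd Gaussian noise sd for PBM intensities; `NULL` uses the
#'   sd of the noiseless scores.
#' @param n_probes number of PBM probes.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, genome_length = 6e5L, n_chrom = 1L,
                         masked_fraction = 0, base_comp = rep(0.25, 4),
                         n_peaks = 500L, peak_width = 200L,
                         window_width = 100L, offset = 500L,
                         site_rate = 0.9, motif = default_true_motif(),
                         n_decoys = 9L, decoy_magnitude = 0.25,
                         pbm_noise_sd = NULL, n_probes = 2000L) {
  stopifnot(length(base_comp) == 4, all(base_comp >= 0),
            abs(sum(base_comp) - 1) < 1e-6,
            masked_fraction >= 0, masked_fraction < 1,
            site_rate >= 0, site_rate <= 1, is_pwm(motif),
            genome_length >= n_peaks * (peak_width + offset + window_width))
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 n_chrom = as.integer(n_chrom),
                 masked_fraction = masked_fraction, base_comp = base_comp,
                 n_peaks = as.integer(n_peaks), peak_width = as.integer(peak_width),
                 window_width = as.integer(window_width),
                 offset = as.integer(offset), site_rate = site_rate,
                 motif = motif, n_decoys = as.integer(n_decoys),
                 decoy_magnitude = decoy_magnitude,
                 pbm_noise_sd = pbm_noise_sd, n_probes = as.integer(n_probes)),
            class = "fixture_spec")
}

#' The default implanted motif
#'
#' A 10 bp motif with consensus `ACGTACGTAC` and the information-content
#' profile of a typical eukaryotic TF site: a near-deterministic 7 bp core
#' (consensus probability 0.95 at positions 2-8) flanked by degenerate
#' positions (consensus probability 0.5 at positions 1, 9, 10), ~12.1 bits in
#' total.
#'
#' @return A [pwm] named `TRUE_MOTIF` with `source_db` `"SYNTH"`.
#' @export
default_true_motif <- function() {
  cons <- match(strsplit("ACGTACGTAC", "")[[1]], DNA_BASES)
  major <- c(0.5, rep(0.95, 7), 0.5, 0.5)
  m <- vapply(seq_along(cons), function(j) {
    col <- rep((1 - major[j]) / 3, 4)
    col[cons[j]] <- major[j]
    col
  }, numeric(4))
  pwm(m, name = "TRUE_MOTIF", source_db = "SYNTH")
}

#' Generate a synthetic genome
#'
#' I.i.d. background sequence with the spec's base composition; a
#' `masked_fraction` of positions is emitted lowercase in contiguous random
#' intervals (emulating soft-masked repeats).
#'
#' @param spec a [fixture_spec].
#' @return List with `genome` (named character vector) and `masked`
#'   (data.frame `chrom`, `start`, `end` of masked intervals, 0-based
#'   half-open).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    per <- diff(round(seq(0, spec$genome_length, length.out = spec$n_chrom + 1)))
    genome <- character(spec$n_chrom)
    names(genome) <- paste0("chr", seq_len(spec$n_chrom))
    masked <- list()
    for (i in seq_len(spec$n_chrom)) {
      s <- sample(DNA_BASES, per[i], replace = TRUE, prob = spec$base_comp)
      if (spec$masked_fraction > 0) {
        # evenly spaced non-overlapping intervals so the realized masked
        # fraction matches the spec up to rounding
        mlen <- 200L
        n_int <- max(1L, round(spec$masked_fraction * per[i] / mlen))
        starts <- round((seq_len(n_int) - 0.5) * per[i] / n_int - mlen / 2)
        starts <- pmin(pmax(starts, 0L), per[i] - mlen) + 1L
        for (st in starts) s[st:(st + mlen - 1L)] <- tolower(s[st:(st + mlen - 1L)])
        masked[[i]] <- data.frame(chrom = names(genome)[i],
                                  start = starts - 1L, end = starts - 1L + mlen)
      }
      genome[i] <- paste(s, collapse = "")
    }
    list(genome = genome,
         masked = if (length(masked)) do.call(rbind, masked)
                  else data.frame(chrom = character(), start = integer(),
                                  end = integer()))
  })
}

#' Implant motif sites and emit peaks
#'
#' Lays `n_peaks` non-overlapping peaks on the genome (regular grid with
#' random jitter, leaving room for the downstream negative windows). With
#' probability `site_rate` a site sampled from the true PWM is written into
#' the genome at a uniform random offset inside the peak's central
#' `window_width` bp, on a random strand. Peak score is proportional to site
#' presence plus Gaussian noise.
#'
#' @param genome named character vector (from [make_genome]).
#' @param spec a [fixture_spec].
#' @return List with the modified `genome`, `peaks` (a `peaks` data.frame)
#'   and `truth` (data.frame: peak name, chrom, site start, strand, site
#'   sequence; one row per implanted site).
#' @export
implant_peaks <- function(genome, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- motif_length(spec$motif)
  w <- spec$window_width
  need <- spec$peak_width + spec$offset + w   # room per peak incl. negatives
  with_seed(spec$seed + 1L, {
    lens <- nchar(genome)
    n_per <- round(spec$n_peaks * lens / sum(lens))
    n_per[1] <- n_per[1] + spec$n_peaks - sum(n_per)
    chars <- lapply(genome, function(g) strsplit(g, "")[[1]])
    peaks <- list(); truth <- list()
    for (ci in seq_along(genome)) {
      if (n_per[ci] < 1L) next
      stride <- (lens[ci] - 100L) %/% n_per[ci]
      if (stride < need)
        stop("genome too short for ", n_per[ci], " peaks on ",
             names(genome)[ci])
      jitter <- sample.int(stride - need + 1L, n_per[ci], replace = TRUE) - 1L
      starts <- 50L + (seq_len(n_per[ci]) - 1L) * stride + jitter
      has_site <- stats::runif(n_per[ci]) < spec$site_rate
      for (j in seq_len(n_per[ci])) {
        ps <- starts[j]
        name <- sprintf("%s_peak_%d", names(genome)[ci], j)
        center <- ps + spec$peak_width %/% 2L
        if (has_site[j]) {
          win_start <- center - w %/% 2L
          site_start <- win_start + sample.int(w - k + 1L, 1L) - 1L
          site <- sample_site(spec$motif)
          strand <- sample(c("+", "-"), 1L)
          written <- if (strand == "+") site else revcomp_string(site)
          chars[[ci]][(site_start + 1L):(site_start + k)] <-
            strsplit(written, "")[[1]]
          truth[[length(truth) + 1L]] <- data.frame(
            peak = name, chrom = names(genome)[ci], site_start = site_start,
            strand = strand, site_seq = site, stringsAsFactors = FALSE)
        }
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = names(genome)[ci], start = ps, end = ps + spec$peak_width,
          name = name,
          score = 50 + 100 * has_site[j] + stats::rnorm(1, sd = 5),
          stringsAsFactors = FALSE)
      }
    }
    pk <- do.call(rbind, peaks)
    list(genome = vapply(chars, paste, character(1), collapse = ""),
         peaks = peaks_df(pk$chrom, pk$start, pk$end, pk$name, pk$score),
         truth = if (length(truth)) do.call(rbind, truth)
                 else data.frame(peak = character(), chrom = character(),
                                 site_start = integer(), strand = character(),
                                 site_seq = character()))
  })
}

sample_site <- function(motif) {
  p <- unclass(motif)
  paste(vapply(seq_len(ncol(p)), function(j)
    sample(DNA_BASES, 1L, prob = p[, j]), character(1)), collapse = "")
}

revcomp_string <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
        collapse = "")
}

#' Decoy motifs
#'
#' Column-permuted, Dirichlet-perturbed copies of a motif, standing in for
#' competing database entries. `magnitude = 0` permutes columns only; larger
#' magnitudes draw each column from a Dirichlet centered on the permuted
#' column with concentration `1/magnitude` (so total-variation distance from
#' the original grows with magnitude).
#'
#' @param motif the template [pwm].
#' @param n number of decoys.
#' @param magnitude perturbation magnitude >= 0.
#' @param seed integer seed.
#' @return List of `n` [pwm]s named `DECOY_1..n`, `source_db` `"DECOYDB"`.
#' @export
make_decoys <- function(motif, n, magnitude = 0.25, seed = 1L) {
  stopifnot(is_pwm(motif), n >= 1, magnitude >= 0)
  p <- unclass(motif)
  k <- ncol(p)
  with_seed(seed, lapply(seq_len(n), function(i) {
    perm <- if (k > 1) sample.int(k) else 1L
    m <- p[, perm, drop = FALSE]
    if (magnitude > 0) {
      m <- apply(m, 2, function(col) {
        g <- stats::rgamma(4, shape = pmax(col, 1e-6) / magnitude)
        if (sum(g) == 0) col else g / sum(g)
      })
    }
    d <- pwm(m, name = sprintf("DECOY_%d", i), source_db = "DECOYDB",
             tol = 1e-6)
    attr(d, "perm") <- perm   # column map back to the template
    d
  }))
}

#' PBM-like probe table
#'
#' Random probes with intensity = single-strand sum occupancy of the true
#' motif plus Gaussian noise; with zero noise the intensity equals the score
#' exactly.
#'
#' @param spec a [fixture_spec].
#' @param motif scoring motif (default the spec's true motif).
#' @param probe_length probe length in bp (default 36).
#' @return A `pbm_probes` data.frame (`probe_id`, `sequence`, `intensity`).
#' @export
make_pbm <- function(spec, motif = spec$motif, probe_length = 36L) {
  stopifnot(inherits(spec, "fixture_spec"),
            probe_length >= motif_length(motif))
  with_seed(spec$seed + 2L, {
    seqs <- vapply(seq_len(spec$n_probes), function(i)
      paste(sample(DNA_BASES, probe_length, replace = TRUE,
                   prob = spec$base_comp), collapse = ""), character(1))
    score <- vapply(seqs, function(s)
      sum_occupancy(motif, s, strand = "single"), numeric(1),
      USE.NAMES = FALSE)
    sd <- spec$pbm_noise_sd %||% stats::sd(score)
    structure(data.frame(probe_id = sprintf("probe_%05d", seq_along(seqs)),
                         sequence = seqs,
                         intensity = score + stats::rnorm(length(seqs), sd = sd),
                         stringsAsFactors = FALSE),
              class = c("pbm_probes", "data.frame"))
  })
}

#' Build the full benchmark fixture
#'
#' Runs the whole construction: genome, implanted peaks, top-peak selection
#' (masked peaks excluded when the genome has masking), centered positive
#' windows, matched downstream negatives, dinucleotide-shuffled negatives,
#' and the motif panel (true motif + decoys).
#'
#' @param spec a [fixture_spec].
#' @return List with `motifs` (true motif first, then decoys), `positives`,
#'   `negatives_downstream`, `negatives_shuffled` ([sequence_set]s), `peaks`
#'   (selected top peaks), `signal` (peak scores aligned to the positives),
#'   `truth`, `genome` and the `spec`.
#' @export
build_fixture <- function(spec = fixture_spec()) {
  g <- make_genome(spec)
  imp <- implant_peaks(g$genome, spec)
  top <- select_top_peaks(imp$peaks, spec$n_peaks, genome = imp$genome,
                          exclude_masked = spec$masked_fraction > 0)
  wins <- make_positive_windows(top, spec$window_width)
  pair <- make_downstream_negatives(wins, spec$offset, genome = imp$genome)
  pos <- extract_sequences(pair$positives, imp$genome, "positive")
  neg <- extract_sequences(pair$negatives, imp$genome, "negative")
  shuf <- shuffle_set(pos, spec$seed + 3L)
  list(motifs = c(list(spec$motif),
                  make_decoys(spec$motif, spec$n_decoys,
                              spec$decoy_magnitude, spec$seed + 4L)),
       positives = pos, negatives_downstream = neg,
       negatives_shuffled = shuf, peaks = pair$positives,
       signal = pair$positives$score, truth = imp$truth,
       genome = imp$genome, spec = spec)
}
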