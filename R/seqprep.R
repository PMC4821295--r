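#' Labeled sequence set
#'
#' A collection of equal-length DNA sequences with a positive/negative role,
#' the unit the scoring and ranking functions operate on.
#'
#' @param ids character vector of unique identifiers.
#' @param seqs character vector of DNA strings (A, C, G, T, N), all of equal
#'   length.
#' @param label "positive" or "negative".
#' @return An object of class `sequence_set`: a list with fields `label`,
#'   `width`, `id`, `seq`.
#' @export
sequence_set <- function(ids, seqs, label = c("positive", "negative")) {
  label <- match.arg(label)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (!length(seqs)) stop("empty sequence set")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("all sequences must have equal length; got widths ",
         paste(unique(widths), collapse = ", "))
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequences may only contain A, C, G, T, N")
  if (anyDuplicated(ids))
    warning("duplicate sequence ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(label = label, width = widths[1], id = ids, seq = seqs),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d %s sequences of %d bp\n",
              length(x$seq), x$label, x$width))
  invisible(x)
}

#' @export
length.sequence_set <- function(x) length(x$seq)

#' Read/write sequence sets and genomes as FASTA
#'
#' `read_genome_fasta()` returns a named character vector of chromosome
#' sequences with original case preserved (lowercase marks soft-masked,
#' i.e. repeat, bases). `read_fasta_set()`/`write_fasta_set()` round-trip a
#' [sequence_set].
#'
#' @param path FASTA file path.
#' @name fasta-io
NULL

#' @rdname fasta-io
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  g <- as.character(x)
  names(g) <- sub("\\s.*$", "", names(x))
  g
}

#' @rdname fasta-io
#' @param label set label for the sequences read.
#' @export
read_fasta_set <- function(path, label = c("positive", "negative")) {
  x <- Biostrings::readBStringSet(path)
  sequence_set(sub("\\s.*$", "", names(x)), as.character(x),
               label = match.arg(label))
}

#' @rdname fasta-io
#' @param set a [sequence_set].
#' @export
write_fasta_set <- function(set, path) {
  stopifnot(inherits(set, "sequence_set"))
  x <- Biostrings::BStringSet(stats::setNames(set$seq, set$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname fasta-io
#' @param genome named character vector of chromosome sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(genome), path)
  invisible(path)
}

#' Read ChIP-seq peaks from a BED file
#'
#' Coordinates are taken as 0-based half-open (BED standard) and kept that
#' way throughout the package.
#'
#' @param path tab-delimited BED-like file with at least 3 columns.
#' @param score_column 1-based index of the numeric peak-signal column
#'   (default 5, the BED score field).
#' @return A data.frame of class `peaks` with columns `chrom`, `start`,
#'   `end`, `name`, `score`, in file order.
#' @export
read_bed_peaks <- function(path, score_column = 5L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!any(nzchar(trimws(readLines(path, warn = FALSE)))))
    return(empty_peaks())
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           comment.char = "#", quote = "",
                           blank.lines.skip = TRUE)
  if (!nrow(raw)) return(empty_peaks())
  if (ncol(raw) < 3L) stop("BED file must have at least 3 columns")
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinate at line ",
         which(is.na(start) | is.na(end))[1])
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end at line ", bad[1], " of ", path)
  if (score_column > ncol(raw))
    stop("score column ", score_column, " absent (file has ",
         ncol(raw), " columns)")
  score <- suppressWarnings(as.numeric(raw[[score_column]]))
  if (anyNA(score))
    stop("non-numeric score at line ", which(is.na(score))[1])
  peaks_df(chrom = raw[[1]], start = start, end = end,
           name = if (ncol(raw) >= 4L && score_column != 4L) raw[[4]] else
             paste0("peak_", seq_len(nrow(raw))),
           score = score)
}

peaks_df <- function(chrom, start, end, name, score) {
  structure(data.frame(chrom = as.character(chrom), start = as.integer(start),
                       end = as.integer(end), name = as.character(name),
                       score = as.numeric(score), stringsAsFactors = FALSE),
            class = c("peaks", "data.frame"))
}

empty_peaks <- function() {
  peaks_df(character(), integer(), integer(), character(), numeric())
}

#' Write peaks as BED5
#'
#' @param peaks a `peaks` data.frame.
#' @param path output path.
#' @export
write_bed_peaks <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end", "name", "score")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Select the highest-scoring peaks
#'
#' Emulates the benchmark construction step of keeping the top-n peaks by
#' signal, optionally discarding peaks whose genomic span touches any
#' soft-masked (lowercase) base first. Ties in score are broken by
#' (chrom, start) ascending so the selection is deterministic.
#'
#' @param peaks a `peaks` data.frame.
#' @param n number of peaks to keep.
#' @param genome named character vector (see [read_genome_fasta]); required
#'   when `exclude_masked = TRUE` and used to drop peaks beyond chromosome
#'   ends.
#' @param exclude_masked drop peaks overlapping lowercase genome bases before
#'   ranking.
#' @return A `peaks` data.frame of at most `n` rows, sorted by score
#'   descending.
#' @export
select_top_peaks <- function(peaks, n, genome = NULL, exclude_masked = FALSE) {
  stopifnot(n >= 1)
  if (!nrow(peaks)) return(peaks)
  if (!is.null(genome)) {
    known <- peaks$chrom %in% names(genome)
    if (!all(known))
      stop("chromosome(s) absent from genome: ",
           paste(unique(peaks$chrom[!known]), collapse = ", "))
    ends <- nchar(genome)[peaks$chrom]
    inb <- peaks$end <= ends & peaks$start >= 0
    if (!all(inb)) {
      warning(sum(!inb), " peak(s) beyond chromosome end skipped")
      peaks <- peaks[inb, , drop = FALSE]
    }
  }
  if (exclude_masked) {
    if (is.null(genome)) stop("exclude_masked requires a genome")
    spans <- substr(genome[peaks$chrom], peaks$start + 1L, peaks$end)
    keep <- !grepl("[a-z]", spans)
    peaks <- peaks[keep, , drop = FALSE]
  }
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  out <- peaks[ord[seq_len(min(n, nrow(peaks)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fixed-width windows centered on peaks
#'
#' Builds the positive set intervals: width-bp windows centered on each
#' peak's midpoint (ENCODE uniform peaks carry no summit column, so the
#' midpoint is the computable center; `summit_offset` shifts the center
#' relative to the peak start when summit information exists).
#'
#' @inheritParams select_top_peaks
#' @param width window width in bp.
#' @param summit_offset optional integer vector (recycled): summit position
#'   relative to peak start; `NULL` uses the midpoint.
#' @return A `peaks` data.frame of equal length; windows that would extend
#'   past the chromosome start are dropped with a warning (keeping widths
#'   uniform).
#' @export
make_positive_windows <- function(peaks, width, summit_offset = NULL) {
  stopifnot(width >= 1)
  if (!nrow(peaks)) return(peaks)
  center <- if (is.null(summit_offset))
    (peaks$start + peaks$end) %/% 2L
  else peaks$start + as.integer(summit_offset)
  start <- center - width %/% 2L
  keep <- start >= 0
  if (!all(keep))
    warning(sum(!keep), " window(s) extending past chromosome start dropped")
  out <- peaks_df(peaks$chrom[keep], start[keep], start[keep] + width,
                  peaks$name[keep], peaks$score[keep])
  rownames(out) <- NULL
  out
}

#' Matched downstream negative intervals
#'
#' For each positive window `[s, e)` the negative window is
#' `[e + offset, e + offset + (e - s))`: same chromosome, same width, same
#' count, located `offset` bp downstream (increasing coordinate) of the
#' positive window end.
#'
#' @param positives a `peaks` data.frame of positive windows.
#' @param offset gap in bp between positive end and negative start
#'   (default 500).
#' @param genome optional genome used to drop out-of-bounds negatives; the
#'   paired positive is dropped too so the sets stay matched.
#' @return A list with elements `negatives` and `positives` (both `peaks`
#'   data.frames of equal row count).
#' @export
make_downstream_negatives <- function(positives, offset = 500L,
                                      genome = NULL) {
  stopifnot(offset >= 0)
  width <- positives$end - positives$start
  neg <- peaks_df(positives$chrom, positives$end + offset,
                  positives$end + offset + width,
                  paste0(positives$name, "_neg"), positives$score)
  if (!is.null(genome)) {
    ends <- nchar(genome)[neg$chrom]
    keep <- !is.na(ends) & neg$end <= ends
    if (!all(keep))
      warning(sum(!keep), " negative window(s) beyond chromosome end; ",
              "pair(s) dropped")
    neg <- neg[keep, , drop = FALSE]
    positives <- positives[keep, , drop = FALSE]
    rownames(neg) <- rownames(positives) <- NULL
  }
  list(positives = positives, negatives = neg)
}

#' Extract interval sequences from a genome
#'
#' @param intervals a `peaks` data.frame (0-based half-open coordinates).
#' @param genome named character vector from [read_genome_fasta].
#' @param label set label for the result.
#' @return A [sequence_set]; sequences uppercased, ids `chrom:start-end`, in
#'   interval order.
#' @export
extract_sequences <- function(intervals, genome,
                              label = c("positive", "negative")) {
  label <- match.arg(label)
  missing_chr <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  ends <- nchar(genome)[intervals$chrom]
  if (any(intervals$end > ends | intervals$start < 0))
    stop("interval(s) out of chromosome bounds")
  seqs <- toupper(substr(genome[intervals$chrom],
                         intervals$start + 1L, intervals$end))
  ids <- sprintf("%s:%d-%d", intervals$chrom, intervals$start, intervals$end)
  sequence_set(ids, seqs, label = label)
}

#' Dinucleotide shuffle of a DNA sequence
#'
#' Altschul-Erickson Eulerian-path shuffle: returns a random permutation of
#' the sequence that preserves the exact multiset of overlapping
#' dinucleotides (and therefore the mononucleotide composition) as well as
#' the first and last characters. `N` is treated as a fifth symbol, so
#' dinucleotides involving `N` are preserved too. Deterministic for a given
#' seed.
#'
#' @param sequence DNA string (length >= 2) over A, C, G, T, N.
#' @param seed integer seed.
#' @return A shuffled DNA string of equal length.
#' @export
dinucleotide_shuffle <- function(sequence, seed) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n < 2L) stop("sequence must have length >= 2")
  if (any(!chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence may only contain A, C, G, T, N")
  with_seed(seed, paste(eulerian_shuffle(chars), collapse = ""))
}

# Altschul & Erickson (1985): pick, for every vertex except the terminal one,
# a random "last exit" edge; accept when the chosen edges form a tree rooted
# at the terminal vertex (every vertex reaches it), then emit each vertex's
# remaining edges in random order with the tree edge last and walk the
# Eulerian path from the first character.
eulerian_shuffle <- function(chars) {
  n <- length(chars)
  verts <- unique(chars)
  if (length(verts) == 1L) return(chars)
  from <- chars[-n]
  to <- chars[-1L]
  last <- chars[n]
  succ <- split(to, factor(from, levels = verts))
  need_tree <- setdiff(names(succ)[lengths(succ) > 0L], last)

  repeat {
    tree <- vapply(need_tree, function(v) {
      s <- succ[[v]]
      s[sample.int(length(s), 1L)]
    }, character(1))
    ok <- all(vapply(need_tree, function(v) {
      seen <- character(0)
      while (v != last) {
        if (v %in% seen || !v %in% need_tree) return(FALSE)
        seen <- c(seen, v)
        v <- tree[[v]]
      }
      TRUE
    }, logical(1)))
    if (ok) break
  }

  ordered <- succ
  for (v in names(succ)) {
    s <- succ[[v]]
    if (!length(s)) next
    if (v %in% need_tree) {
      idx <- which(s == tree[[v]])[1]
      rest <- s[-idx]
      ordered[[v]] <- c(if (length(rest)) rest[sample.int(length(rest))],
                        tree[[v]])
    } else {
      ordered[[v]] <- s[sample.int(length(s))]
    }
  }

  out <- character(n)
  out[1] <- chars[1]
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  v <- chars[1]
  for (i in 2:n) {
    nxt <- ordered[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nxt
    v <- nxt
  }
  out
}

#' Dinucleotide-shuffled negative set
#'
#' Applies [dinucleotide_shuffle] to every record of a positive set, with
#' per-record seeds derived as `seed + record index`, and relabels the result
#' negative.
#'
#' @param positives a [sequence_set].
#' @param seed integer base seed.
#' @return A negative [sequence_set] of equal width and count, ids suffixed
#'   `_shuf`.
#' @export
shuffle_set <- function(positives, seed) {
  stopifnot(inherits(positives, "sequence_set"))
  shuf <- vapply(seq_along(positives$seq), function(i)
    dinucleotide_shuffle(positives$seq[i], seed + i), character(1))
  sequence_set(paste0(positives$id, "_shuf"), shuf, label = "negative")
}

#' Read a protein binding microarray (PBM) probe table
#'
#' Tab-separated table with probe id, probe sequence and spot intensity
#' columns. Probes with non-finite intensity are dropped with a warning.
#'
#' @param path TSV path; a header line is auto-detected.
#' @param probe_length required probe length in bp (default 36).
#' @param id_col,seq_col,intensity_col 1-based column indices.
#' @return A data.frame of class `pbm_probes` with columns `probe_id`,
#'   `sequence`, `intensity`, in file order.
#' @export
read_pbm_table <- function(path, probe_length = 36L, id_col = 1L,
                           seq_col = 2L, intensity_col = 3L) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  toks <- strsplit(first, "\t")[[1]]
  has_header <- length(toks) >= intensity_col &&
    is.na(suppressWarnings(as.numeric(toks[intensity_col])))
  raw <- utils::read.table(path, sep = "\t", header = has_header,
                           colClasses = "character", quote = "")
  ids <- raw[[id_col]]
  seqs <- toupper(raw[[seq_col]])
  intensity <- suppressWarnings(as.numeric(raw[[intensity_col]]))
  bad_len <- nchar(seqs) != probe_length
  if (any(bad_len))
    stop("probe(s) with sequence length != ", probe_length, ": ",
         paste(utils::head(ids[bad_len], 3), collapse = ", "))
  drop <- !is.finite(intensity)
  if (any(drop)) {
    warning(sum(drop), " probe(s) with missing intensity dropped")
    ids <- ids[!drop]; seqs <- seqs[!drop]; intensity <- intensity[!drop]
  }
  structure(data.frame(probe_id = ids, sequence = seqs,
                       intensity = intensity, stringsAsFactors = FALSE),
            class = c("pbm_probes", "data.frame"))
}

#' Split PBM probes into positive and negative sequence sets
#'
#' Intensity-quantile rule: the top `q` fraction of probes by intensity form
#' the positive set and the bottom `q` fraction the negative set.
#'
#' @param probes a `pbm_probes` data.frame.
#' @param q quantile fraction in (0, 0.5] (default 0.05).
#' @return List with [sequence_set]s `positives` and `negatives` and the
#'   positive probes' `intensities`.
#' @export
pbm_partition <- function(probes, q = 0.05) {
  stopifnot(q > 0, q <= 0.5)
  n <- nrow(probes)
  k <- max(1L, floor(q * n))
  ord <- order(-probes$intensity)
  top <- probes[ord[seq_len(k)], ]
  bot <- probes[ord[seq.int(n - k + 1L, n)], ]
  list(positives = sequence_set(top$probe_id, top$sequence, "positive"),
       negatives = sequence_set(bot$probe_id, bot$sequence, "negative"),
       intensities = top$intensity)
}

# Run expr with a local RNG state: seeds the generator, restores the caller's
# .Random.seed afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
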