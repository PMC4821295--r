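DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix (PWM)
#'
#' A PWM models transcription factor binding specificity as a 4 x L matrix of
#' per-position base probabilities over the DNA alphabet A, C, G, T.
#'
#' @param matrix numeric 4 x L matrix; rows in A, C, G, T order, every column
#'   summing to 1. Columns deviating from 1 by at most `tol` are renormalized;
#'   larger deviations are an error.
#' @param name motif identifier.
#' @param source_db free-text database label (e.g. "JASPAR", "ZLAB").
#' @param nsites optional positive integer: number of sites the motif was
#'   built from.
#' @param tol maximum tolerated column-sum deviation before rejection.
#' @return An object of class `pwm`: the probability matrix with attributes
#'   `name`, `source_db` and `nsites`.
#' @export
pwm <- function(matrix, name = "motif", source_db = "", nsites = NULL,
                tol = 1e-3) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4L)
    stop("PWM must have 4 rows (A, C, G, T); got ", nrow(m))
  if (ncol(m) < 1L) stop("PWM must have at least one column")
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0))
    stop("PWM '", name, "': entries must be nonnegative and finite")
  cs <- colSums(m)
  bad <- which(abs(cs - 1) > tol)
  if (length(bad))
    stop("PWM '", name, "': column(s) ", paste(bad, collapse = ", "),
         " sum to ", paste(signif(cs[bad], 6), collapse = ", "),
         " (deviation > ", tol, ")")
  m <- sweep(m, 2, cs, "/")
  rownames(m) <- DNA_BASES
  colnames(m) <- NULL
  structure(m, name = as.character(name), source_db = as.character(source_db),
            nsites = if (!is.null(nsites)) as.integer(nsites),
            class = c("pwm", "matrix", "array"))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%s), length %d\n", motif_name(x),
              if (nzchar(attr(x, "source_db"))) attr(x, "source_db") else "no db",
              motif_length(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' @rdname pwm
#' @param x object to test or query.
#' @export
is_pwm <- function(x) inherits(x, "pwm")

#' @rdname pwm
#' @export
motif_name <- function(x) attr(x, "name")

#' @rdname pwm
#' @export
motif_length <- function(x) ncol(x)

#' Convert a count matrix to a PWM
#'
#' Applies Laplace-style smoothing: entry (b, j) becomes
#' (counts\[b, j\] + pseudocount) / (column total + 4 * pseudocount).
#'
#' @param counts nonnegative 4 x L numeric matrix, rows in A, C, G, T order.
#' @param pseudocount nonnegative scalar added to every cell (default 1).
#' @inheritParams pwm
#' @return A [pwm].
#' @export
counts_to_pwm <- function(counts, pseudocount = 1, name = "motif",
                          source_db = "") {
  m <- as.matrix(counts)
  if (nrow(m) != 4L) stop("count matrix must have 4 rows (A, C, G, T)")
  if (anyNA(m) || any(m < 0)) stop("counts must be nonnegative")
  if (length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single nonnegative number")
  tot <- colSums(m) + 4 * pseudocount
  if (any(tot <= 0))
    stop("every column total + 4*pseudocount must be positive")
  p <- sweep(m + pseudocount, 2, tot, "/")
  pwm(p, name = name, source_db = source_db,
      nsites = if (pseudocount == 0 && all(m == round(m)))
        max(1L, round(max(colSums(m)))))
}

#' Motif descriptive statistics
#'
#' Information content (IC) of column j is 2 + sum_b p_bj * log2(p_bj) bits,
#' with 0 * log(0) taken as 0; total IC sums over columns and the mean
#' normalizes by motif length.
#'
#' @param motif a [pwm].
#' @return A list of class `motif_stats` with fields `name`, `length`,
#'   `ic_total` and `ic_mean` (bits).
#' @export
motif_stats <- function(motif) {
  stopifnot(is_pwm(motif))
  p <- unclass(motif)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + colSums(plogp)
  structure(list(name = motif_name(motif), length = ncol(p),
                 ic_total = sum(ic), ic_mean = sum(ic) / ncol(p),
                 ic_per_column = unname(ic)),
            class = "motif_stats")
}

#' @export
print.motif_stats <- function(x, ...) {
  cat(sprintf("%s: length %d bp, IC %.3f bits total, %.3f bits/position\n",
              x$name, x$length, x$ic_total, x$ic_mean))
  invisible(x)
}

#' Read motifs from a MEME minimal text file
#'
#' Parses the MEME minimal motif format: an optional `MEME version` line,
#' optional `ALPHABET` and `Background letter frequencies` lines, then one or
#' more `MOTIF` blocks each carrying a `letter-probability matrix` header and
#' one row of 4 probabilities (A C G T) per motif position. Matrix rows
#' become PWM columns.
#'
#' @param path path to a MEME-format text file.
#' @param source_db database label attached to every motif read.
#' @return A list of [pwm] objects, in file order. The file's background
#'   frequencies (uniform 0.25 when absent) are attached as attribute
#'   `background`.
#' @export
read_meme <- function(path, source_db = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    # frequencies may be on the same line or the next
    bgline <- sub("^Background letter frequencies.*?:?\\s*", "", lines[bg_at[1]])
    if (!grepl("[0-9]", bgline) && bg_at[1] < length(lines))
      bgline <- lines[bg_at[1] + 1L]
    toks <- strsplit(trimws(bgline), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(toks))
    vals <- nums[!is.na(nums)]
    if (length(vals) >= 4) {
      names(vals) <- toks[which(!is.na(nums)) - 1L]
      background <- vals[seq_len(4)]
      if (all(DNA_BASES %in% names(vals))) background <- vals[DNA_BASES]
      background <- unname(background)
    }
  }
  alpha_at <- grep("^ALPHABET", lines)
  if (length(alpha_at)) {
    alpha <- gsub("\\s", "", sub("^ALPHABET\\s*=?\\s*", "", lines[alpha_at[1]]))
    if (nzchar(alpha) && toupper(alpha) != "ACGT")
      stop("only the DNA alphabet ACGT is supported; file declares '",
           alpha, "'")
  }

  motif_at <- grep("^MOTIF\\b", lines)
  motifs <- vector("list", length(motif_at))
  bounds <- c(motif_at, length(lines) + 1L)
  for (i in seq_along(motif_at)) {
    block <- lines[motif_at[i]:(bounds[i + 1L] - 1L)]
    ids <- strsplit(trimws(block[1]), "\\s+")[[1]][-1]
    name <- if (length(ids)) ids[1] else paste0("motif_", i)
    hdr_at <- grep("letter-probability matrix", block)
    if (!length(hdr_at))
      stop("motif '", name, "': no letter-probability matrix header")
    hdr <- block[hdr_at[1]]
    w <- as_meme_field(hdr, "w")
    nsites <- as_meme_field(hdr, "nsites")
    rows <- list()
    for (off in seq.int(hdr_at[1] + 1L, length.out = length(block) - hdr_at[1])) {
      ln <- trimws(block[off])
      if (!nzchar(ln)) { if (length(rows)) break else next }
      if (grepl("^(MOTIF|URL|letter-)", ln)) break
      toks <- strsplit(ln, "\\s+")[[1]]
      nums <- suppressWarnings(as.numeric(toks))
      if (anyNA(nums) || length(nums) != 4L)
        stop("motif '", name, "': malformed matrix row at line ",
             motif_at[i] + off - 1L, ": '", ln, "' (expected 4 numbers)")
      rows[[length(rows) + 1L]] <- nums
    }
    if (!length(rows)) stop("motif '", name, "': empty probability matrix")
    if (!is.na(w) && w != length(rows))
      stop("motif '", name, "': header says w=", w, " but ",
           length(rows), " rows found")
    m <- do.call(cbind, rows)  # file rows are positions -> PWM columns
    motifs[[i]] <- pwm(m, name = name, source_db = source_db,
                       nsites = if (!is.na(nsites)) nsites)
  }
  attr(motifs, "background") <- background
  motifs
}

as_meme_field <- function(header, field) {
  pat <- paste0(".*\\b", field, "\\s*=\\s*([0-9.eE+-]+).*")
  if (grepl(pat, header)) as.numeric(sub(pat, "\\1", header)) else NA_real_
}

#' Write motifs to a MEME minimal text file
#'
#' @param motifs a [pwm] or list of [pwm] objects.
#' @param path output file path.
#' @param background 4 background probabilities (A, C, G, T).
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  if (is_pwm(motifs)) motifs <- list(motifs)
  if (!length(motifs)) stop("empty motif list")
  stopifnot(all(vapply(motifs, is_pwm, logical(1))),
            length(background) == 4, abs(sum(background) - 1) < 1e-6)
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           paste(sprintf("%s %.6f", DNA_BASES, background), collapse = " "),
           "")
  for (m in motifs) {
    ns <- attr(m, "nsites")
    hdr <- sprintf("letter-probability matrix: alength= 4 w= %d%s",
                   ncol(m), if (!is.null(ns)) sprintf(" nsites= %d", ns) else "")
    rows <- apply(unclass(m), 2, function(col)
      paste(sprintf("%.6f", col), collapse = " "))
    out <- c(out, paste("MOTIF", motif_name(m)), hdr, rows, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a plain-text count matrix
#'
#' Whitespace-delimited numeric matrix, either 4 rows (A, C, G, T) by L
#' columns or its transpose (L rows by 4 columns).
#'
#' @inheritParams read_meme
#' @inheritParams counts_to_pwm
#' @return A [pwm] via [counts_to_pwm].
#' @export
read_counts <- function(path, pseudocount = 1, name = NULL, source_db = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(m) != 4L && ncol(m) == 4L) m <- t(m)
  if (nrow(m) != 4L) stop("count matrix must be 4 x L or L x 4")
  counts_to_pwm(m, pseudocount = pseudocount,
                name = if (is.null(name))
                  tools::file_path_sans_ext(basename(path)) else name,
                source_db = source_db)
}

#' Reverse complement of a PWM
#'
#' @param motif a [pwm].
#' @return The [pwm] of the reverse strand (rows swapped A<->T, C<->G,
#'   columns reversed).
#' @export
reverse_complement_pwm <- function(motif) {
  stopifnot(is_pwm(motif))
  m <- unclass(motif)[4:1, rev(seq_len(ncol(motif))), drop = FALSE]
  pwm(m, name = motif_name(motif), source_db = attr(motif, "source_db"),
      nsites = attr(motif, "nsites"))
}
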