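#' Bundle one benchmark dataset
#'
#' A dataset is one (cell line x negative-set choice) benchmark: a positive
#' set, optionally a matched negative set (required for AUC/MNCP), and
#' optionally a peak-signal/intensity vector aligned to the positives
#' (required for Pearson/Spearman).
#'
#' @param id dataset identifier.
#' @param positives positive [sequence_set].
#' @param negatives negative [sequence_set] or `NULL`.
#' @param signal optional numeric vector, one value per positive sequence.
#' @return A list of class `benchmark_dataset`.
#' @export
benchmark_dataset <- function(id, positives, negatives = NULL,
                              signal = NULL) {
  stopifnot(inherits(positives, "sequence_set"))
  if (!is.null(negatives)) stopifnot(inherits(negatives, "sequence_set"))
  if (!is.null(signal) && length(signal) != length(positives$seq))
    stop("signal length must match the number of positive sequences")
  structure(list(id = as.character(id), positives = positives,
                 negatives = negatives, signal = signal),
            class = "benchmark_dataset")
}

#' Assess all motifs of one transcription factor
#'
#' For every (motif, scoring function, statistic, dataset) combination,
#' scores the dataset and computes the statistic; per-motif summaries are the
#' mean over datasets (cell-line averaging), computed before normalization
#' and ranking. Ranks are assigned within each (function, statistic) slice by
#' descending summary value, ties broken by motif name.
#'
#' @param tf transcription factor name.
#' @param motifs list of [pwm] objects (carrying `source_db` labels).
#' @param datasets list of [benchmark_dataset] objects.
#' @param functions scoring function names (see [score_set]).
#' @param statistics statistic names among `"auc"`, `"mncp"`, `"pearson"`,
#'   `"spearman"`.
#' @inheritParams score_set
#' @return An object of class `assessment_result`: list with `tf`, `values`
#'   (long data.frame: motif, source_db, fun, statistic, dataset, value),
#'   `summary` (motif, source_db, fun, statistic, value, n_datasets, norm,
#'   rank) and `skipped` (motif/dataset pairs excluded because the motif was
#'   longer than the sequence width).
#' @export
assess_tf <- function(tf, motifs, datasets,
                      functions = c("gomer", "energy", "sumoc", "maxoc",
                                    "ama", "sumlog"),
                      statistics = c("auc", "mncp"),
                      strand = c("both", "single"),
                      background = rep(0.25, 4), mu = 0, pseudo = 1e-3) {
  strand <- match.arg(strand)
  if (is_pwm(motifs)) motifs <- list(motifs)
  stopifnot(length(motifs) >= 1, length(datasets) >= 1)
  bad <- setdiff(statistics, RANK_STATISTICS)
  if (length(bad))
    stop("unknown statistic(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(RANK_STATISTICS, collapse = ", "))
  bad <- setdiff(functions, SCORING_FUNCTIONS)
  if (length(bad))
    stop("unknown scoring function(s): ", paste(bad, collapse = ", "))
  ds_ids <- vapply(datasets, function(d) d$id, character(1))
  if (anyDuplicated(ds_ids)) stop("duplicate dataset ids")

  mnames <- vapply(motifs, motif_name, character(1))
  if (anyDuplicated(mnames))
    stop("duplicate motif names: ",
         paste(unique(mnames[duplicated(mnames)]), collapse = ", "))
  rows <- list()
  skipped <- list()
  for (d in datasets) {
    stopifnot(inherits(d, "benchmark_dataset"))
    need_neg <- any(statistics %in% c("auc", "mncp"))
    if (need_neg && is.null(d$negatives))
      stop("dataset '", d$id, "' has no negative set but AUC/MNCP requested")
    enc_pos <- lapply(d$positives$seq, encode_dna)
    enc_neg <- if (!is.null(d$negatives)) lapply(d$negatives$seq, encode_dna)
    for (m in motifs) {
      if (motif_length(m) > d$positives$width) {
        warning("motif '", motif_name(m), "' longer than sequences of ",
                "dataset '", d$id, "'; excluded")
        skipped[[length(skipped) + 1L]] <-
          data.frame(motif = motif_name(m), dataset = d$id)
        next
      }
      sp <- score_matrix(m, enc_pos, functions, strand = strand,
                         background = background, mu = mu, pseudo = pseudo)
      sn <- if (!is.null(enc_neg))
        score_matrix(m, enc_neg, functions, strand = strand,
                     background = background, mu = mu, pseudo = pseudo)
      for (fn in functions) {
        for (st in statistics) {
          val <- switch(st,
            auc = auc(sp[, fn], sn[, fn]),
            mncp = mncp(sp[, fn], sn[, fn]),
            pearson = if (is.null(d$signal)) NA_real_ else
              pearson_cor(sp[, fn], d$signal),
            spearman = if (is.null(d$signal)) NA_real_ else
              spearman_cor(sp[, fn], d$signal))
          rows[[length(rows) + 1L]] <- data.frame(
            motif = motif_name(m), source_db = attr(m, "source_db"),
            fun = fn, statistic = st, dataset = d$id, value = val,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  values <- do.call(rbind, rows)
  values <- values[!is.na(values$value), , drop = FALSE]
  rownames(values) <- NULL
  summary <- summarize_assessment(values)
  structure(list(tf = tf, values = values, summary = summary,
                 skipped = if (length(skipped)) do.call(rbind, skipped)),
            class = "assessment_result")
}

summarize_assessment <- function(values) {
  agg <- stats::aggregate(value ~ motif + source_db + fun + statistic,
                          data = values, FUN = mean)
  n <- stats::aggregate(value ~ motif + source_db + fun + statistic,
                        data = values, FUN = length)
  agg$n_datasets <- n$value
  pieces <- split(agg, list(agg$fun, agg$statistic), drop = TRUE)
  pieces <- lapply(pieces, function(p) {
    p$norm <- if (max(p$value) > 0) p$value / max(p$value) else NA_real_
    p <- p[order(-p$value, p$motif), , drop = FALSE]
    p$rank <- seq_len(nrow(p))
    p
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$fun, out$statistic, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.assessment_result <- function(x, ...) {
  cat(sprintf("assessment of %s: %d motifs, %d dataset(s), %d function(s), %d statistic(s)\n",
              x$tf, length(unique(x$summary$motif)),
              length(unique(x$values$dataset)),
              length(unique(x$summary$fun)),
              length(unique(x$summary$statistic))))
  top <- x$summary[x$summary$rank == 1, c("fun", "statistic", "motif", "value")]
  cat("top-ranked motif per (function, statistic):\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' Pairwise rank correlation across functions or datasets
#'
#' Spearman rank correlation of per-motif values between every pair of
#' levels of the chosen axis: scoring functions (how much the choice of
#' scoring function reorders motifs) or datasets (cell lines, or negative-set
#' choices represented as separate datasets).
#'
#' @param result an `assessment_result` from [assess_tf].
#' @param axis `"functions"` or `"datasets"`.
#' @param statistic statistic to use (default `"auc"`).
#' @param fun scoring function to hold fixed when `axis = "datasets"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
crossranks <- function(result, axis = c("functions", "datasets"),
                       statistic = "auc", fun = "gomer") {
  axis <- match.arg(axis)
  stopifnot(inherits(result, "assessment_result"))
  df <- if (axis == "functions") {
    s <- result$summary[result$summary$statistic == statistic, ]
    stats::reshape(s[, c("motif", "fun", "value")], idvar = "motif",
                   timevar = "fun", direction = "wide")
  } else {
    v <- result$values[result$values$statistic == statistic &
                         result$values$fun == fun, ]
    stats::reshape(v[, c("motif", "dataset", "value")], idvar = "motif",
                   timevar = "dataset", direction = "wide")
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  colnames(mat) <- sub("^value\\.", "", colnames(mat))
  if (ncol(mat) < 2) stop("need at least 2 levels on axis '", axis, "'")
  if (nrow(mat) < 3) stop("need at least 3 motifs for rank correlation")
  cc <- stats::cor(mat, method = "spearman", use = "pairwise.complete.obs")
  diag(cc) <- 1
  cc
}

#' Rank motif databases across transcription factors
#'
#' For every TF and database, the best motif (highest summary value for the
#' statistic being reported) represents the database; within each TF the
#' database values are normalized by the maximum, and each database's
#' normalized values are averaged over the TFs where it is present.
#'
#' @param results list of `assessment_result` objects (one per TF) whose
#'   motifs carry `source_db` labels.
#' @param functions,statistics subsets to report (default: all present).
#' @return data.frame of class `db_ranking`: `fun`, `statistic`, `database`,
#'   `mean_norm`, `n_tfs`, `rank` (ties share the minimum rank).
#' @export
rank_databases <- function(results, functions = NULL, statistics = NULL) {
  stopifnot(length(results) >= 1)
  summaries <- lapply(results, function(r) {
    stopifnot(inherits(r, "assessment_result"))
    cbind(tf = r$tf, r$summary)
  })
  all_sum <- do.call(rbind, summaries)
  all_sum <- all_sum[nzchar(all_sum$source_db), , drop = FALSE]
  if (!nrow(all_sum)) stop("no motif carries a source_db label")
  if (is.null(functions)) functions <- unique(all_sum$fun)
  if (is.null(statistics)) statistics <- unique(all_sum$statistic)
  out <- list()
  for (fn in functions) {
    for (st in statistics) {
      s <- all_sum[all_sum$fun == fn & all_sum$statistic == st, ]
      if (!nrow(s)) next
      # best motif per (tf, db), then max-normalize within each tf
      best <- stats::aggregate(value ~ tf + source_db, data = s, FUN = max)
      norm <- do.call(rbind, lapply(split(best, best$tf), function(p) {
        p$norm <- normalize_by_max(p$value)
        p
      }))
      agg <- stats::aggregate(norm ~ source_db, data = norm, FUN = mean)
      cnt <- stats::aggregate(norm ~ source_db, data = norm, FUN = length)
      res <- data.frame(fun = fn, statistic = st, database = agg$source_db,
                        mean_norm = agg$norm, n_tfs = cnt$norm,
                        stringsAsFactors = FALSE)
      res$rank <- rank(-res$mean_norm, ties.method = "min")
      out[[length(out) + 1L]] <- res[order(res$rank, res$database), ]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("db_ranking", "data.frame")
  res
}

#' Run a full assessment from a config file
#'
#' The config is a YAML file naming inputs and options:
#' ```yaml
#' tf: FOXA1
#' motifs:
#'   - {file: motifs_a.meme, db: JASPAR}
#'   - {file: motifs_b.meme, db: ZLAB}
#' datasets:
#'   - {id: helas3, positive: pos.fa, negative: neg.fa}
#'   - {id: shuffle, positive: pos.fa, negative: shuffle}
#' functions: [gomer, energy, sumoc]
#' statistics: [auc, mncp]
#' strand: both
#' mu: 0
#' seed: 7
#' ```
#' A dataset `negative` of `"shuffle"` generates the dinucleotide-shuffled
#' negative set from that dataset's positives with the config seed. All input
#' files are checked before any computation starts; reruns with the same
#' config and seed are byte-identical.
#'
#' @param config path to the YAML config.
#' @param out output directory (created if needed).
#' @return Invisibly, a list with the `assessment_result`, the database
#'   ranking, and the paths written: `values.tsv`, `summary.tsv`,
#'   `crossranks_functions.tsv` (when >= 2 functions and >= 3 motifs),
#'   `db_ranking.tsv`, `run_log.json`.
#' @export
run_config <- function(config, out) {
  cfg <- yaml::read_yaml(config)
  for (field in c("tf", "motifs", "datasets"))
    if (is.null(cfg[[field]])) stop("config field missing: ", field)
  functions <- unlist(cfg$functions %||% c("gomer", "energy"))
  statistics <- unlist(cfg$statistics %||% c("auc", "mncp"))
  bad <- setdiff(statistics, RANK_STATISTICS)
  if (length(bad))
    stop("config field 'statistics': unknown name(s) ",
         paste(bad, collapse = ", "))
  bad <- setdiff(functions, SCORING_FUNCTIONS)
  if (length(bad))
    stop("config field 'functions': unknown name(s) ",
         paste(bad, collapse = ", "))
  seed <- cfg$seed %||% 1L
  base <- dirname(normalizePath(config))
  locate <- function(p) if (file.exists(p)) p else file.path(base, p)

  # validate every input before computing anything
  motif_files <- vapply(cfg$motifs, function(m) locate(m$file), character(1))
  ds_files <- unlist(lapply(cfg$datasets, function(d)
    c(locate(d$positive),
      if (!identical(d$negative, "shuffle") && !is.null(d$negative))
        locate(d$negative),
      if (!is.null(d$signal)) locate(d$signal))))
  missing <- c(motif_files, ds_files)[!file.exists(c(motif_files, ds_files))]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))

  warnings_seen <- character(0)
  result <- withCallingHandlers({
    motifs <- unlist(lapply(seq_along(cfg$motifs), function(i)
      read_meme(motif_files[i], source_db = cfg$motifs[[i]]$db %||% "")),
      recursive = FALSE)
    datasets <- lapply(cfg$datasets, function(d) {
      pos <- read_fasta_set(locate(d$positive), "positive")
      neg <- if (identical(d$negative, "shuffle")) shuffle_set(pos, seed)
        else if (!is.null(d$negative))
          read_fasta_set(locate(d$negative), "negative")
      sig <- if (!is.null(d$signal))
        utils::read.table(locate(d$signal), header = FALSE)[[1]]
      benchmark_dataset(d$id, pos, neg, sig)
    })
    assess_tf(cfg$tf, motifs, datasets, functions = functions,
              statistics = statistics,
              strand = cfg$strand %||% "both", mu = cfg$mu %||% 0)
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, name) {
    p <- file.path(out, name)
    for (j in seq_along(df))
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.12g", df[[j]])
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(write_tsv(result$values, "values.tsv"),
             write_tsv(result$summary, "summary.tsv"))
  if (length(functions) >= 2 && length(unique(result$summary$motif)) >= 3) {
    cc <- crossranks(result, "functions", statistic = statistics[1])
    paths <- c(paths, write_tsv(
      cbind(fun = rownames(cc), as.data.frame(round(cc, 12))),
      "crossranks_functions.tsv"))
  }
  dbr <- rank_databases(list(result))
  paths <- c(paths, write_tsv(dbr, "db_ranking.tsv"))
  log_path <- file.path(out, "run_log.json")
  jsonlite::write_json(
    list(package = "motifbench",
         version = as.character(utils::packageVersion("motifbench")),
         tf = cfg$tf, functions = functions, statistics = statistics,
         strand = cfg$strand %||% "both", mu = cfg$mu %||% 0, seed = seed,
         n_motifs = length(unique(result$summary$motif)),
         datasets = vapply(cfg$datasets, `[[`, character(1), "id"),
         warnings = warnings_seen),
    log_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(result = result, db_ranking = dbr,
                 paths = c(paths, log_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
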