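make_bed <- function(lines) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_bed_peaks parses BED5 with 0-based half-open coordinates", {
  f <- make_bed("chr1\t100\t200\tp1\t50")
  pk <- read_bed_peaks(f, score_column = 5)
  expect_equal(pk$chrom, "chr1")
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 200L)
  expect_equal(pk$score, 50)

  empty <- make_bed(character(0))
  expect_equal(nrow(read_bed_peaks(empty)), 0)

  ooo <- make_bed(c("chr1\t0\t10\ta\t3", "chr2\t5\t15\tb\t9",
                    "chr1\t20\t30\tc\t1"))
  pk <- read_bed_peaks(ooo)
  expect_equal(pk$name, c("a", "b", "c"))  # file order preserved
  expect_equal(pk$score, c(3, 9, 1))
})

test_that("read_bed_peaks rejects bad records", {
  expect_error(read_bed_peaks(make_bed("chr1\t200\t100\tp\t1")), "line 1")
  expect_error(read_bed_peaks(make_bed("chr1\t1\t2\tp\txx")), "score")
  expect_error(read_bed_peaks(make_bed("chr1\t1\t2")), "score column 5")
})

test_that("select_top_peaks keeps the n highest-scoring peaks deterministically", {
  pk <- read_bed_peaks(make_bed(sprintf("chr1\t%d\t%d\tp%d\t%d",
                                        (1:10) * 100, (1:10) * 100 + 10,
                                        1:10, 1:10)))
  top <- select_top_peaks(pk, 3)
  expect_equal(top$score, c(10, 9, 8))

  # score ties broken by (chrom, start)
  tied <- read_bed_peaks(make_bed(c("chr2\t5\t10\tb\t7", "chr1\t5\t10\ta\t7",
                                    "chr1\t1\t4\tc\t7")))
  expect_equal(select_top_peaks(tied, 2)$name, c("c", "a"))
})

test_that("select_top_peaks drops soft-masked peaks before ranking", {
  genome <- c(chr1 = paste0(strrep("A", 50), strrep("a", 10), strrep("A", 40)))
  pk <- read_bed_peaks(make_bed(c("chr1\t45\t60\tmasked\t100",
                                  "chr1\t0\t20\tclean\t1")))
  top <- select_top_peaks(pk, 2, genome = genome, exclude_masked = TRUE)
  expect_equal(top$name, "clean")
  # without masking filter the masked peak wins
  expect_equal(select_top_peaks(pk, 1, genome = genome)$name, "masked")
})

test_that("top-500 of 600 peaks with 100 masked returns exactly the 500 unmasked", {
  withr::local_seed(8)
  base <- paste(sample(c("A", "C", "G", "T"), 700 * 30, TRUE), collapse = "")
  chars <- strsplit(base, "")[[1]]
  starts <- (0:599) * 30L
  masked_idx <- sample.int(600, 100)
  for (i in masked_idx) {
    at <- starts[i] + 5L
    chars[(at + 1):(at + 5)] <- tolower(chars[(at + 1):(at + 5)])
  }
  genome <- c(chrS = paste(chars, collapse = ""))
  pk <- peaksframe <- data.frame(chrom = "chrS", start = starts,
                                 end = starts + 20L,
                                 name = paste0("p", 1:600),
                                 score = runif(600))
  class(pk) <- c("peaks", "data.frame")
  top <- select_top_peaks(pk, 500, genome = genome, exclude_masked = TRUE)
  expect_equal(nrow(top), 500)
  expect_true(!any(top$name %in% paste0("p", masked_idx)))
})

test_that("make_positive_windows centers fixed-width windows on peak midpoints", {
  pk <- read_bed_peaks(make_bed("chr1\t100\t200\tp\t5"))
  w50 <- make_positive_windows(pk, 50)
  expect_equal(c(w50$start, w50$end), c(125L, 175L))
  w100 <- make_positive_windows(pk, 100)
  expect_equal(c(w100$start, w100$end), c(100L, 200L))
  w250 <- make_positive_windows(pk, 250)
  expect_equal(c(w250$start, w250$end), c(25L, 275L))

  near_start <- read_bed_peaks(make_bed("chr1\t0\t20\tp\t5"))
  expect_warning(out <- make_positive_windows(near_start, 100), "dropped")
  expect_equal(nrow(out), 0)
})

test_that("downstream negatives are matched in count, width and disjoint", {
  pos <- make_positive_windows(read_bed_peaks(make_bed("chr1\t100\t200\tp\t5")), 50)
  neg <- make_downstream_negatives(pos, 500)$negatives
  expect_equal(c(neg$start, neg$end), c(675L, 725L))

  abut <- make_downstream_negatives(pos, 0)$negatives
  expect_equal(abut$start, pos$end)

  withr::local_seed(14)
  starts <- sort(sample.int(100000, 500)) * 20L
  many <- structure(data.frame(chrom = "chr1", start = starts,
                               end = starts + 100L,
                               name = paste0("p", 1:500), score = 1),
                    class = c("peaks", "data.frame"))
  pair <- make_downstream_negatives(many, 500)
  expect_equal(nrow(pair$negatives), 500)
  expect_equal(pair$negatives$end - pair$negatives$start,
               many$end - many$start)
  expect_true(all(pair$negatives$start >= many$end))  # disjoint
})

test_that("out-of-bounds negatives drop their paired positives too", {
  genome <- c(chr1 = strrep("A", 1000))
  pos <- structure(data.frame(chrom = "chr1", start = c(100L, 400L),
                              end = c(200L, 500L), name = c("a", "b"),
                              score = c(1, 2)),
                   class = c("peaks", "data.frame"))
  expect_warning(pair <- make_downstream_negatives(pos, 500, genome = genome),
                 "dropped")
  expect_equal(pair$positives$name, "a")
  expect_equal(nrow(pair$negatives), 1)
})

test_that("extract_sequences uppercases and ids intervals", {
  genome <- c(chrX = "acgTGCAtt")
  iv <- structure(data.frame(chrom = "chrX", start = 0L, end = 4L,
                             name = "i", score = 0),
                  class = c("peaks", "data.frame"))
  set <- extract_sequences(iv, genome, "positive")
  expect_equal(set$seq, "ACGT")
  expect_equal(set$id, "chrX:0-4")

  full <- structure(data.frame(chrom = "chrX", start = 0L, end = 9L,
                               name = "f", score = 0),
                    class = c("peaks", "data.frame"))
  expect_equal(extract_sequences(full, genome)$seq, "ACGTGCATT")

  iv$chrom <- "chrZ"
  expect_error(extract_sequences(iv, genome), "chrZ")

  dup <- rbind(full, full)
  expect_warning(two <- extract_sequences(dup, genome), "duplicate")
  expect_equal(two$seq[1], two$seq[2])
})

test_that("dinucleotide_shuffle preserves dinucleotide multisets and endpoints", {
  expect_equal(dinucleotide_shuffle("AAAA", 1), "AAAA")
  # ACAC admits a single Eulerian arrangement with these endpoints
  for (seed in 1:25)
    expect_equal(dinucleotide_shuffle("ACAC", seed), "ACAC")

  withr::local_seed(99)
  for (rep in 1:200) {
    s <- random_seq(sample(10:120, 1), with_n = rep %% 4 == 0)
    out <- dinucleotide_shuffle(s, seed = rep)
    expect_equal(nchar(out), nchar(s))
    expect_equal(substr(out, 1, 1), substr(s, 1, 1))
    expect_equal(substr(out, nchar(out), nchar(out)),
                 substr(s, nchar(s), nchar(s)))
    expect_equal(oracle_dinuc_counts(out), oracle_dinuc_counts(s))
  }
  expect_error(dinucleotide_shuffle("A", 1), "length")
})

test_that("dinucleotide_shuffle is deterministic per seed and leaves the RNG alone", {
  s <- random_seq(80)
  expect_equal(dinucleotide_shuffle(s, 7), dinucleotide_shuffle(s, 7))
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(dinucleotide_shuffle(s, 7)); after <- runif(1)
  expect_equal(before, after)
})

test_that("shuffle_set shuffles per record and relabels negative", {
  withr::local_seed(4)
  pos <- sequence_set(paste0("s", 1:3),
                      replicate(3, random_seq(40)), "positive")
  neg <- shuffle_set(pos, 11)
  expect_equal(neg$label, "negative")
  expect_equal(neg$width, 40)
  expect_length(neg$seq, 3)
  expect_equal(shuffle_set(pos, 11), neg)          # determinism
  for (i in 1:3)
    expect_equal(oracle_dinuc_counts(neg$seq[i]),
                 oracle_dinuc_counts(pos$seq[i]))
})

test_that("read_pbm_table parses and validates probe tables", {
  f <- withr::local_tempfile(fileext = ".tsv")
  seqs <- vapply(1:2, function(i) strrep("ACGT", 9), character(1))
  writeLines(c("id\tsequence\tintensity",
               sprintf("pr1\t%s\t120.5", seqs[1]),
               sprintf("pr2\t%s\t80.25", seqs[2])), f)
  tab <- read_pbm_table(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$intensity, c(120.5, 80.25))

  writeLines(c(sprintf("pr1\t%s\t120.5", seqs[1]),
               sprintf("pr2\t%s\tNA", seqs[2])), f)
  expect_warning(tab <- read_pbm_table(f), "dropped")
  expect_equal(tab$probe_id, "pr1")

  writeLines(sprintf("pr1\tACGT\t5"), f)
  expect_error(read_pbm_table(f), "pr1")
})

test_that("read_pbm_table keeps all probes of a large fixture in order", {
  withr::local_seed(31)
  f <- withr::local_tempfile(fileext = ".tsv")
  ids <- sprintf("probe_%03d", 1:100)
  writeLines(sprintf("%s\t%s\t%.3f", ids,
                     replicate(100, random_seq(36)), rnorm(100, 100, 10)), f)
  tab <- read_pbm_table(f)
  expect_equal(nrow(tab), 100)
  expect_equal(tab$probe_id, ids)
})

test_that("pbm_partition takes top/bottom intensity quantiles", {
  withr::local_seed(2)
  probes <- data.frame(probe_id = sprintf("p%03d", 1:200),
                       sequence = replicate(200, random_seq(36)),
                       intensity = seq_len(200))
  part <- pbm_partition(probes, q = 0.05)
  expect_length(part$positives$seq, 10)
  expect_length(part$negatives$seq, 10)
  expect_equal(sort(part$intensities), 191:200)
  expect_equal(part$positives$label, "positive")
})

test_that("sequence FASTA round-trip preserves ids and sequences", {
  withr::local_seed(17)
  f <- withr::local_tempfile(fileext = ".fa")
  set <- sequence_set(paste0("s", 1:5), replicate(5, random_seq(30)),
                      "positive")
  write_fasta_set(set, f)
  back <- read_fasta_set(f, "positive")
  expect_equal(back$id, set$id)
  expect_equal(back$seq, set$seq)

  g <- c(chr1 = "ACGTacgtNN")
  write_genome_fasta(g, f)
  expect_equal(read_genome_fasta(f), g)  # case preserved
})
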