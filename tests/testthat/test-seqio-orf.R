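test_that("FASTA reading normalizes sequences and validates input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">tx1 description here", "augC", ">tx2", "ACGRacgt"), fa)
  recs <- read_transcripts(fa)
  expect_equal(recs$id, c("tx1", "tx2"))
  expect_equal(recs$seq, c("ATGC", "ACGNACGT"))
  expect_equal(recs$length, c(4L, 8L))

  # reading twice gives identical records
  expect_identical(recs, read_transcripts(fa))

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_equal(nrow(read_transcripts(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">tx1", "ACGT"), bad)
  expect_error(read_transcripts(bad), "before first header")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_transcripts(dup), "Duplicate")

  expect_error(read_transcripts(tempfile()), "not found")
  expect_error(normalize_dna("ACGJ", id = "tx9"), "tx9")
})

test_that("FASTA writer round-trips and wraps at 60 columns", {
  tx <- tibble::tibble(id = c("a", "b"),
                       seq = c(strrep("ACGT", 40L), "ACGTN"))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_transcripts(tx, fa)
  lines <- readLines(fa)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60L))
  back <- read_transcripts(fa)
  expect_equal(back$seq, tx$seq)
})

test_that("translation follows the standard genetic code with N->X", {
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("ATGGCTTAA"), "MA")
  expect_match(translate_cds("ATGNNATAA"), "X")
  expect_equal(translate_cds("AT"), "")
  expect_equal(translate_cds("ATGGCTT"), "MA") # trailing partial codon dropped
})

test_that("longest-ORF finder handles complete, fallback and degenerate cases", {
  o <- find_longest_orf("ATGAAATAG")
  expect_equal(o[c("start", "end", "frame")], list(start = 0L, end = 9L, frame = 0L))
  expect_true(o$has_start && o$has_stop)
  expect_equal(o$protein, "MK")

  # no ATG at all: full sequence in frame 0
  o <- find_longest_orf("CCCCCCCC")
  expect_false(o$has_start)
  expect_false(o$has_stop)
  expect_equal(c(o$start, o$end), c(0L, 8L))

  # ATG but no in-frame stop: stretch to the end, whole codons
  o <- find_longest_orf("CCATGAAACC")
  expect_true(o$has_start)
  expect_false(o$has_stop)
  expect_equal(c(o$start, o$end), c(2L, 8L))
  expect_equal((o$end - o$start) %% 3L, 0)
})

test_that("longest-ORF finder matches the brute-force span enumeration", {
  set.seed(101)
  for (i in 1:150) {
    seq <- random_dna(sample(50:1500, 1))
    got <- find_longest_orf(seq)
    want <- orf_oracle(seq)
    expect_equal(got[c("start", "end", "frame", "has_start", "has_stop")],
                 want[c("start", "end", "frame", "has_start", "has_stop")],
                 info = seq)
    if (got$has_start && got$has_stop) {
      expect_equal(3L * (nchar(got$protein) + 1L), got$end - got$start)
    }
  }
})
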