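test_that("hexamer table counts in-frame hexamers and normalizes", {
  tab <- build_hexamer_table("ATGGCAGCATAA", "ACGTACGTACGT")
  counted <- tab$hexamer[tab$coding_freq > 0]
  expect_setequal(counted, c("ATGGCA", "GCAGCA", "GCATAA"))
  expect_equal(tab$coding_freq[tab$coding_freq > 0], rep(1 / 3, 3))
  expect_equal(sum(tab$coding_freq), 1, tolerance = 1e-9)
  expect_equal(sum(tab$noncoding_freq), 1, tolerance = 1e-9)
  expect_equal(nrow(tab), 4096L)

  # a 5-nt sequence contributes nothing
  tab2 <- build_hexamer_table(c("ATGGCAGCATAA", "ACGTA"), "ACGTACGTACGT")
  expect_equal(tab2$coding_freq, tab$coding_freq)
  expect_error(build_hexamer_table(character(), "ACGTAC"), "non-empty")
})

test_that("hexamer table round-trips through TSV", {
  tab <- build_hexamer_table(c("ATGGCAGCATAA", "ATGAAATTTCCCTAG"),
                             c("ACGTACGTACGT"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hexamer_table(tab, tsv)
  back <- read_hexamer_table(tsv)
  expect_equal(back$coding_freq, tab$coding_freq)
  expect_equal(back$noncoding_freq, tab$noncoding_freq)
})

test_that("hexamer score implements the mean log-ratio with fallbacks", {
  # identical class frequencies: every ratio is 1, score 0
  tab <- build_hexamer_table("ATGGCAGCATAA", "ATGGCAGCATAA")
  expect_equal(hexamer_score("ATGGCAGCATAA", tab), 0)

  # short input scores 0 by the m == 0 convention
  expect_equal(hexamer_score("ATGCC", tab), 0)

  # hand-built table vs direct-formula oracle, incl. -1/+1 fallbacks
  tab2 <- build_hexamer_table(c("ATGGCAGCATAA", "ATGAAATTTTAG"),
                              c("ACGTACGTACGTACG"))
  for (orf in c("ATGGCAGCATAA", "ATGAAATTTTAG", "ACGTACGTACGT")) {
    expect_equal(hexamer_score(orf, tab2), naive_hexamer_score(orf, tab2))
  }

  # N-containing hexamers are skipped
  expect_equal(hexamer_score("ATGNCAGCATAA", tab2),
               naive_hexamer_score("ATGNCAGCATAA", tab2))
})

test_that("hexamer score and CTD match brute-force oracles on random input", {
  set.seed(202)
  train_c <- replicate(20, random_dna(120))
  train_n <- replicate(20, random_dna(120))
  tab <- build_hexamer_table(train_c, train_n)
  for (i in 1:60) {
    seq <- random_dna(sample(10:400, 1))
    expect_equal(hexamer_score(seq, tab), naive_hexamer_score(seq, tab))
    expect_equal(unname(ctd_features(seq)), naive_ctd(seq))
  }
})

test_that("CTD features follow the stated conventions", {
  f <- ctd_features("AAAAAAAAAA")
  expect_equal(unname(f[paste0("comp_", c("A", "C", "G", "T"))]), c(1, 0, 0, 0))
  expect_true(all(f[grepl("^trans_", names(f))] == 0))
  expect_equal(unname(f[grepl("^dist_A", names(f))]), c(0.1, 0.3, 0.5, 0.8, 1.0))
  expect_true(all(f[grepl("^dist_[CGT]", names(f))] == 0))

  # composition sums to 1 without N, less with N
  expect_equal(sum(ctd_features("ACGTACGT")[1:4]), 1)
  expect_lt(sum(ctd_features("ACGTNNNN")[1:4]), 1)
})

test_that("Fickett score matches an independent implementation and its bounds", {
  tab <- read_pkg_table("fickett_testcode.tsv")
  lo <- sum(sapply(split(tab, interaction(tab$kind, tab$base)),
                   function(s) min(s$probability * s$weight)))
  hi <- sum(sapply(split(tab, interaction(tab$kind, tab$base)),
                   function(s) max(s$probability * s$weight)))
  fixed <- strrep("ATGGC", 12L) # 60 nt
  expect_equal(fickett_score(fixed), naive_fickett(fixed))
  set.seed(303)
  for (i in 1:25) {
    seq <- random_dna(sample(30:500, 1))
    s <- fickett_score(seq)
    expect_equal(s, naive_fickett(seq))
    expect_gte(s, lo)
    expect_lte(s, hi)
  }
  # upstream normalization makes case irrelevant
  expect_equal(fickett_score(normalize_dna("atggcatggca")),
               fickett_score("ATGGCATGGCA"))
})

test_that("GRAVY averages Kyte-Doolittle hydropathy excluding X", {
  expect_equal(gravy("A"), 1.8)
  expect_equal(gravy("AV"), 3.0)
  expect_equal(gravy("AX"), gravy("A"))
  expect_warning(g0 <- gravy("XX"), "empty or all-unknown")
  expect_equal(g0, 0)
  set.seed(404)
  for (i in 1:20) {
    p <- paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"), 50,
                      replace = TRUE), collapse = "")
    expect_equal(gravy(p), naive_gravy(p))
  }
})

test_that("isoelectric point zeroes the net charge and orders acid vs base", {
  for (p in c("G", "RRRR", "DDDD", "MKVLLAYRDE")) {
    pi_hat <- isoelectric_point(p)
    expect_lt(abs(naive_pi(p) - pi_hat), 0.01)
  }
  expect_gt(isoelectric_point("RRRR"), isoelectric_point("DDDD"))
})

test_that("instability index sums dipeptide weights", {
  diwv <- read_pkg_table("instability_diwv.tsv")
  gg <- diwv[diwv$residue == "G", "G"]
  expect_equal(instability_index("GG"), 5 * gg)
  set.seed(505)
  for (i in 1:20) {
    p <- paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"), 50,
                      replace = TRUE), collapse = "")
    expect_equal(instability_index(p), naive_instability(p))
  }
  expect_warning(ii <- instability_index("G"), "shorter than 2")
  expect_equal(ii, 0)
})

test_that("basic ORF features and GC content", {
  orf <- find_longest_orf("ATGAAATAG")
  f <- orf_basic_features(orf, 20L)
  expect_equal(unname(f), c(9, 0.45, 1))
  fb <- orf_basic_features(find_longest_orf("CCCCCC"), 6L)
  expect_equal(unname(fb[c("orf_coverage", "orf_integrity")]), c(1, -1))
  expect_error(orf_basic_features(orf, 0L), "positive")

  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCAT"), 0.5)
  expect_equal(gc_content("GCNN"), 0.5) # N in denominator only
})

test_that("feature assembly yields the documented widths per group set", {
  set.seed(606)
  tx <- tibble::tibble(
    id = paste0("t", 1:6),
    seq = c(replicate(5, paste0("ACGT", "ATG", random_dna(60), "TAA", "CGTA")),
            random_dna(100)))
  tab <- build_hexamer_table(tx$seq[1:3], tx$seq[4:6])
  emb <- tibble::tibble(id = tx$id)
  emb <- dplyr::bind_cols(emb, tibble::as_tibble(matrix(rnorm(6 * 100), 6,
    dimnames = list(NULL, sprintf("pv_%03d", 1:100)))))

  full <- transcript_features(tx, tab, emb)
  expect_equal(ncol(full) - 1L, 110L)
  ovec <- transcript_features(tx, embeddings = emb, groups = "embedding")
  expect_equal(ncol(ovec) - 1L, 100L)
  nvec <- transcript_features(tx, tab, groups = c("orf", "protein", "rna"))
  expect_equal(ncol(nvec) - 1L, 10L)
  expect_equal(names(nvec)[-1L], classic_feature_names())
  with_ctd <- transcript_features(tx, tab, groups = c("orf", "protein", "rna", "ctd"))
  expect_equal(ncol(with_ctd) - 1L, 40L)

  # identical input, identical output (purity)
  expect_identical(full, transcript_features(tx, tab, emb))

  # missing embedding id is named in the error
  expect_error(transcript_features(tx, tab, emb[-2L, ]), "t2")
})
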