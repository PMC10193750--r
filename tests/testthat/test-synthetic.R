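small_config <- function(seed = 42L, ...) {
  synthetic_config(n_coding = 40L, n_noncoding = 40L,
                   len_range = c(200L, 900L), seed = seed, ...)
}

test_that("simulation produces the requested records, deterministically", {
  cfg <- small_config()
  dat <- simulate_transcripts(cfg)
  expect_equal(nrow(dat), 80L)
  expect_equal(sum(dat$label == "coding"), 40L)
  expect_false(any(duplicated(dat$id)))
  expect_true(all(dat$length >= 200L & dat$length <= 900L + 2L))
  expect_identical(dat, simulate_transcripts(cfg))

  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("cod.fa", "nc.fa", "labels.tsv"))
  simulate_dataset(cfg, paths[1], paths[2], paths[3])
  first <- lapply(paths, readLines)
  simulate_dataset(cfg, paths[1], paths[2], paths[3])
  expect_identical(lapply(paths, readLines), first)
  labs <- utils::read.delim(paths[3])
  expect_equal(nrow(labs), 80L)
  expect_equal(names(labs), c("id", "label"))
})

test_that("coding records carry their planted ORF as the longest ORF", {
  cfg <- synthetic_config(n_coding = 200L, n_noncoding = 0L,
                          len_range = c(200L, 1200L), seed = 42L)
  dat <- simulate_transcripts(cfg)
  orfs <- find_orfs(dat)
  expect_true(all(orfs$orf_start == orfs$planted_start))
  expect_true(all(orfs$orf_end == orfs$planted_end))
  expect_true(all(orfs$has_start & orfs$has_stop))
  expect_true(all(orfs$orf_end - orfs$orf_start >= 90L))
})

test_that("noncoding records respect the ORF-length ceiling", {
  cfg <- small_config()
  dat <- simulate_transcripts(cfg)
  nc <- find_orfs(dat[dat$label == "noncoding", ])
  expect_true(all(nc$orf_end - nc$orf_start <= cfg$max_nc_orf))
})

test_that("sORF planting guarantees a short ORF in every noncoding record", {
  cfg <- synthetic_config(n_coding = 5L, n_noncoding = 30L,
                          len_range = c(200L, 600L), sorf_prob = 1,
                          seed = 7L)
  dat <- simulate_transcripts(cfg)
  nc <- dat[dat$label == "noncoding", ]
  has_sorf <- vapply(nc$seq, function(s) {
    # enumerate complete ORF spans with the oracle-style scan
    n <- nchar(s)
    for (fr in 0:2) {
      i <- fr + 1L
      while (i + 2L <= n) {
        if (substr(s, i, i + 2L) == "ATG") {
          j <- i
          while (j + 2L <= n && !(substr(s, j, j + 2L) %in% oracle_stops)) j <- j + 3L
          if (j + 2L <= n) {
            len <- j + 3L - i
            if (len >= 30L && len <= 150L) return(TRUE)
          }
        }
        i <- i + 3L
      }
    }
    FALSE
  }, logical(1))
  expect_true(all(has_sorf))
})

test_that("indel corruption produces hard negatives under the same ceiling", {
  cfg <- synthetic_config(n_coding = 10L, n_noncoding = 15L,
                          len_range = c(200L, 700L), indel_rate = 0.01,
                          seed = 13L)
  dat <- simulate_transcripts(cfg)
  nc <- find_orfs(dat[dat$label == "noncoding", ])
  expect_equal(nrow(nc), 15L)
  expect_true(all(nc$orf_end - nc$orf_start <= cfg$max_nc_orf))
})

test_that("planted coding ORF lengths stochastically dominate noncoding ones", {
  dat <- simulate_transcripts(small_config())
  orfs <- find_orfs(dat)
  cod_len <- with(orfs[orfs$label == "coding", ], orf_end - orf_start)
  nc_len <- with(orfs[orfs$label == "noncoding", ], orf_end - orf_start)
  wt <- stats::wilcox.test(cod_len, nc_len, alternative = "greater",
                           exact = FALSE)
  expect_lt(wt$p.value, 1e-4)
})

test_that("coding sequences score higher on an independently trained hexamer table", {
  # table batch and scoring batch are disjoint halves of one simulated
  # population (the codon-usage regime is a dataset-level property)
  dat <- simulate_transcripts(synthetic_config(
    n_coding = 80L, n_noncoding = 80L, len_range = c(200L, 900L), seed = 42L))
  train <- dat[c(1:40, 81:120), ]
  test <- dat[c(41:80, 121:160), ]
  train_orfs <- find_orfs(train)
  tab <- build_hexamer_table(train_orfs$orf_seq[train_orfs$label == "coding"],
                             train_orfs$seq[train_orfs$label == "noncoding"])
  test_orfs <- find_orfs(test)
  sc <- vapply(test_orfs$orf_seq, hexamer_score, numeric(1), table = tab,
               USE.NAMES = FALSE)
  expect_gt(mean(sc[test_orfs$label == "coding"]),
            mean(sc[test_orfs$label == "noncoding"]))
})

test_that("infeasible configurations are rejected up front", {
  expect_error(synthetic_config(len_range = c(50L, 100L)), ">= 60")
  expect_error(synthetic_config(len_range = c(80L, 100L),
                                utr5_range = c(10L, 20L),
                                utr3_range = c(10L, 20L)), "Infeasible")
  expect_error(synthetic_config(sorf_prob = 1.5), "probabilities")
})
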