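test_that("protein splitting is non-overlapping and drops the remainder", {
  expect_equal(split_protein("MNFLLSWVHWSLALLLYL"),
               c("MNF", "LLS", "WVH", "WSL", "ALL", "LYL"))
  expect_equal(split_protein("MNF"), "MNF")
  expect_equal(split_protein("MNFL"), "MNF")
  expect_equal(split_protein("MN"), character())
  expect_equal(split_protein("MNFL", word_len = 2L), c("MN", "FL"))
})

test_that("corpus construction preserves order and flags degenerate docs", {
  prot <- tibble::tibble(id = c("a", "b", "c"),
                         protein = c("MKVLLA", "MK", "AAAWWW"))
  expect_warning(corpus <- build_corpus(prot), "no words")
  expect_equal(corpus$id, prot$id)
  expect_equal(corpus$words[[1]], c("MKV", "LLA"))
  expect_equal(corpus$words[[2]], character())
  expect_identical(suppressWarnings(build_corpus(prot)),
                   suppressWarnings(build_corpus(prot)))
  expect_error(build_corpus(tibble::tibble(id = c("a", "a"),
                                           protein = c("MKV", "LLA"))),
               "Duplicate")
})

toy_corpus <- function() {
  # two identical documents and one of disjoint words
  prot <- tibble::tibble(
    id = c("twin1", "twin2", "other"),
    protein = c(strrep("MKVLLADEF", 12L), strrep("MKVLLADEF", 12L),
                strrep("WGSTYPHRQ", 12L)))
  build_corpus(prot)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

test_that("PV-DM training is seeded, dimension-true and reproducible", {
  corpus <- toy_corpus()
  m1 <- train_pvdm(corpus, dim = 16L, epochs = 30L, seed = 9L)
  m2 <- train_pvdm(corpus, dim = 16L, epochs = 30L, seed = 9L)
  expect_identical(m1$doc_matrix, m2$doc_matrix)
  expect_identical(m1$word_matrix, m2$word_matrix)
  expect_equal(dim(m1$doc_matrix), c(3L, 16L))
  expect_true(all(is.finite(m1$doc_matrix)))
  expect_true(all(is.finite(m1$word_matrix)))
  # a different seed gives a different model
  m3 <- train_pvdm(corpus, dim = 16L, epochs = 30L, seed = 10L)
  expect_false(identical(m1$doc_matrix, m3$doc_matrix))
  expect_error(train_pvdm(corpus[0L, ]), "empty")
})

test_that("identical documents embed closer than disjoint ones", {
  m <- train_pvdm(toy_corpus(), dim = 16L, epochs = 40L, seed = 5L)
  v <- m$doc_matrix
  twin_sim <- cosine(v["twin1", ], v["twin2", ])
  expect_gt(twin_sim, cosine(v["twin1", ], v["other", ]))
  expect_gt(twin_sim, cosine(v["twin2", ], v["other", ]))
})

test_that("stored-mode embedding retrieval is exact and validates ids", {
  corpus <- toy_corpus()
  m <- train_pvdm(corpus, dim = 8L, epochs = 10L, seed = 2L)
  emb <- embed_documents(m, c("twin2", "other"), mode = "stored")
  expect_equal(emb$id, c("twin2", "other"))
  expect_equal(unlist(emb[1L, -1L], use.names = FALSE),
               unname(m$doc_matrix["twin2", ]))
  expect_error(embed_documents(m, "nope", mode = "stored"), "nope")
})

test_that("inference freezes the model and ranks own documents highest", {
  corpus <- toy_corpus()
  m <- train_pvdm(corpus, dim = 16L, epochs = 40L, seed = 5L)
  word_before <- m$word_matrix
  inferred <- embed_documents(m, corpus, mode = "infer")
  expect_identical(m$word_matrix, word_before)
  expect_equal(ncol(inferred) - 1L, 16L)
  # an inferred vector for a training document is most similar to its own
  # stored vector
  for (doc in c("twin1", "other")) {
    vi <- unlist(inferred[inferred$id == doc, -1L], use.names = FALSE)
    sims <- apply(m$doc_matrix, 1L, cosine, a = vi)
    expect_gt(sims[[doc]], median(sims[names(sims) != doc]))
  }

  # empty-word document stays at the zero vector, with a warning
  empty <- tibble::tibble(id = "e", words = list(character()))
  expect_warning(z <- embed_documents(m, empty, mode = "infer"),
                 "no in-vocabulary")
  expect_equal(unlist(z[1L, -1L], use.names = FALSE), rep(0, 16L))
})

test_that("a PV-DM model round-trips through its text bundle", {
  m <- train_pvdm(toy_corpus(), dim = 8L, epochs = 10L, seed = 2L)
  dir <- withr::local_tempdir()
  save_pvdm(m, dir)
  back <- load_pvdm(dir)
  expect_equal(back$doc_matrix, m$doc_matrix, tolerance = 1e-12)
  expect_equal(back$word_matrix, m$word_matrix, tolerance = 1e-12)
  expect_equal(back$config$dim, m$config$dim)
  expect_equal(back$vocab$word, m$vocab$word)
})

test_that("corpus export writes one document per line", {
  corpus <- toy_corpus()
  f <- withr::local_tempfile(fileext = ".txt")
  write_corpus(corpus, f)
  lines <- readLines(f)
  expect_length(lines, 3L)
  expect_match(lines[1L], "^twin1\tMKV LLA DEF")
})
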