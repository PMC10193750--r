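# Protein "documents" and the PV-DM paragraph-vector model. A protein is
# split into non-overlapping amino-acid words (length 3 by default); each
# split protein forms one document; PV-DM learns a fixed-length vector per
# document alongside the word vectors.

#' Split a protein into non-overlapping words
#'
#' Consecutive non-overlapping substrings of length `word_len` starting at
#' position 0; a trailing remainder shorter than `word_len` is dropped.
#'
#' @param protein An amino-acid string.
#' @param word_len Word length (default 3).
#' @return Character vector of words (possibly empty).
#' @examples
#' split_protein("MNFLLSWVHWSLALLLYL")
#' @export
split_protein <- function(protein, word_len = 3L) {
  assert_scalar_string(protein, "protein")
  if (word_len < 1L) abort("`word_len` must be >= 1.")
  n <- nchar(protein)
  nwords <- n %/% word_len
  if (nwords == 0L) return(character())
  starts <- word_len * (seq_len(nwords) - 1L) + 1L
  substring(protein, starts, starts + word_len - 1L)
}

#' Build a document corpus from proteins
#'
#' One document per protein, in stable input order. Proteins too short to
#' yield a word produce a document with an empty word list (with a warning).
#'
#' @param proteins A tibble with columns `id` and `protein`, or a named
#'   character vector of proteins.
#' @param word_len Word length passed to [split_protein()].
#' @return A tibble with columns `id` and `words` (list column of character
#'   vectors).
#' @export
build_corpus <- function(proteins, word_len = 3L) {
  if (is.character(proteins)) {
    proteins <- tibble(id = names(proteins) %||%
                         as.character(seq_along(proteins)),
                       protein = unname(proteins))
  }
  stopifnot(is.data.frame(proteins), all(c("id", "protein") %in% names(proteins)))
  dup <- proteins$id[duplicated(proteins$id)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate document id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  words <- lapply(proteins$protein, split_protein, word_len = word_len)
  n_empty <- sum(lengths(words) == 0L)
  if (n_empty > 0L) {
    warn(sprintf("%d document(s) have no words (protein shorter than %d).",
                 n_empty, word_len),
         class = "orfvec_degenerate_input")
  }
  tibble(id = proteins$id, words = words)
}

#' Train a PV-DM paragraph-vector model
#'
#' Distributed-memory paragraph vectors: at each position of each document,
#' the paragraph vector and the word vectors inside a window of up to
#' `window` words on each side are combined (averaged) to predict the
#' central word, trained by stochastic gradient descent with negative
#' sampling (5 noise words, unigram^0.75 noise distribution, no
#' frequent-word subsampling). Training is single-threaded with a private
#' seeded RNG, so a fixed seed gives bitwise-identical models.
#'
#' @param corpus A corpus tibble from [build_corpus()].
#' @param dim Vector dimension (default 100).
#' @param window Context window: up to `window` words on each side of the
#'   predicted word (default 4).
#' @param epochs Training passes over the corpus (default 20).
#' @param min_count Words occurring fewer times are dropped from the
#'   vocabulary (default 1: keep all).
#' @param negative Number of negative samples per position (default 5).
#' @param alpha,min_alpha Initial and floor learning rate for the linear
#'   decay (defaults 0.025 and 1e-4).
#' @param seed Integer seed for initialization, window reduction and
#'   negative sampling.
#' @return An object of class `pvdm`: list with `doc_matrix` (documents x
#'   dim, row names = ids), `word_matrix`, `output_matrix`, `vocab`
#'   (tibble of `word`, `count`) and `config`.
#' @export
train_pvdm <- function(corpus, dim = 100L, window = 4L, epochs = 20L,
                       min_count = 1L, negative = 5L, alpha = 0.025,
                       min_alpha = 1e-4, seed = 1L) {
  stopifnot(is.data.frame(corpus), all(c("id", "words") %in% names(corpus)))
  if (nrow(corpus) == 0L) abort("`corpus` is empty.")
  if (dim < 1L || window < 1L) abort("`dim` and `window` must be >= 1.")
  all_words <- unlist(corpus$words, use.names = FALSE)
  if (length(all_words) == 0L) {
    abort("All documents are empty; nothing to train.")
  }
  counts <- sort(table(all_words), decreasing = TRUE)
  counts <- counts[counts >= min_count]
  # deterministic vocabulary order: by count desc, then alphabetically
  vocab <- names(counts)[order(-as.integer(counts), names(counts))]
  vocab_counts <- as.numeric(counts[vocab])
  lookup <- stats::setNames(seq_along(vocab) - 1L, vocab)
  docs <- lapply(corpus$words, function(w) {
    idx <- lookup[w]
    as.integer(idx[!is.na(idx)])
  })
  fit <- pvdm_train_cpp(docs, length(vocab), vocab_counts, as.integer(dim),
                        as.integer(window), as.integer(epochs),
                        as.integer(negative), alpha, min_alpha,
                        as.integer(seed))
  rownames(fit$doc_matrix) <- corpus$id
  rownames(fit$word_matrix) <- vocab
  rownames(fit$output_matrix) <- vocab
  structure(
    list(doc_matrix = fit$doc_matrix,
         word_matrix = fit$word_matrix,
         output_matrix = fit$output_matrix,
         vocab = tibble(word = vocab, count = vocab_counts),
         config = list(dim = as.integer(dim), window = as.integer(window),
                       epochs = as.integer(epochs),
                       min_count = as.integer(min_count),
                       negative = as.integer(negative), alpha = alpha,
                       min_alpha = min_alpha, seed = as.integer(seed),
                       format_version = 1L)),
    class = "pvdm")
}

#' @export
print.pvdm <- function(x, ...) {
  cat(sprintf("PV-DM model: %d documents, %d words, dim %d (window %d, %d epochs, seed %d)\n",
              nrow(x$doc_matrix), nrow(x$word_matrix), x$config$dim,
              x$config$window, x$config$epochs, x$config$seed))
  invisible(x)
}

#' Retrieve or infer document vectors
#'
#' In `stored` mode (the transductive protocol: the documents were part of
#' the training corpus) the trained paragraph vectors are returned; looking
#' up an unknown id is an error. In `infer` mode the word and output
#' matrices are frozen and a fresh zero-initialized paragraph vector is
#' optimized per document for `epochs` seeded passes; documents with no
#' in-vocabulary words keep the zero vector (with a warning).
#'
#' @param model A `pvdm` model from [train_pvdm()].
#' @param docs For `stored` mode, a character vector of ids or a corpus
#'   tibble (its `id` column is used). For `infer` mode, a corpus tibble
#'   from [build_corpus()].
#' @param mode `"stored"` or `"infer"`.
#' @param epochs,seed Inference schedule (defaults: the model's).
#' @return A tibble: `id` plus `dim` numeric columns named `pv_001`, ...
#' @export
embed_documents <- function(model, docs, mode = c("stored", "infer"),
                            epochs = NULL, seed = NULL) {
  stopifnot(inherits(model, "pvdm"))
  mode <- match.arg(mode)
  dim <- model$config$dim
  if (mode == "stored") {
    ids <- if (is.data.frame(docs)) docs$id else docs
    unknown <- setdiff(ids, rownames(model$doc_matrix))
    if (length(unknown) > 0L) {
      abort(sprintf("No stored vector for document id(s): %s",
                    paste(utils::head(unknown, 5L), collapse = ", ")))
    }
    mat <- model$doc_matrix[ids, , drop = FALSE]
  } else {
    stopifnot(is.data.frame(docs), all(c("id", "words") %in% names(docs)))
    lookup <- stats::setNames(seq_len(nrow(model$vocab)) - 1L,
                              model$vocab$word)
    idx <- lapply(docs$words, function(w) {
      i <- lookup[w]
      as.integer(i[!is.na(i)])
    })
    if (any(lengths(idx) == 0L)) {
      warn(sprintf("%d document(s) have no in-vocabulary words; their vectors stay zero.",
                   sum(lengths(idx) == 0L)),
           class = "orfvec_degenerate_input")
    }
    mat <- pvdm_infer_cpp(idx, model$word_matrix, model$output_matrix,
                          model$vocab$count, model$config$window,
                          as.integer(epochs %||% model$config$epochs),
                          model$config$negative, model$config$alpha,
                          model$config$min_alpha,
                          as.integer(seed %||% model$config$seed))
    rownames(mat) <- docs$id
    ids <- docs$id
  }
  colnames(mat) <- pv_names(dim)
  dplyr::bind_cols(tibble(id = ids), as_tibble(mat))
}

pv_names <- function(dim) sprintf("pv_%03d", seq_len(dim))

#' Persist / restore a PV-DM model as plain text
#'
#' Writes the model into a directory as TSV matrices plus a JSON config
#' manifest (format-versioned); `load_pvdm()` restores it.
#'
#' @param model A `pvdm` model.
#' @param dir Directory path (created if needed).
#' @return `save_pvdm()` returns `dir` invisibly; `load_pvdm()` the model.
#' @export
save_pvdm <- function(model, dir) {
  stopifnot(inherits(model, "pvdm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, f) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_mat(model$doc_matrix, "doc_vectors.tsv")
  write_mat(model$word_matrix, "word_vectors.tsv")
  write_mat(model$output_matrix, "output_weights.tsv")
  utils::write.table(model$vocab, file.path(dir, "vocab.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(model$config, file.path(dir, "pvdm_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_pvdm
#' @export
load_pvdm <- function(dir) {
  read_mat <- function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$id
    colnames(m) <- NULL
    m
  }
  config <- jsonlite::read_json(file.path(dir, "pvdm_config.json"),
                                simplifyVector = TRUE)
  vocab <- as_tibble(utils::read.delim(file.path(dir, "vocab.tsv"),
                                       stringsAsFactors = FALSE))
  structure(list(doc_matrix = read_mat("doc_vectors.tsv"),
                 word_matrix = read_mat("word_vectors.tsv"),
                 output_matrix = read_mat("output_weights.tsv"),
                 vocab = vocab, config = config),
            class = "pvdm")
}

#' Export a corpus as one-document-per-line text
#'
#' Each line: the document id, a tab, then space-separated words.
#'
#' @param corpus A corpus tibble from [build_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- paste0(corpus$id, "\t",
                  vapply(corpus$words, paste, character(1), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
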