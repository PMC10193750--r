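# End-to-end orchestration: FASTA/tibble in, fitted model bundle out,
# predictions and metrics tibbles downstream.

muffle_degenerate <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (inherits(w, "orfvec_degenerate_input")) invokeRestart("muffleWarning")
  })
}

#' Train the full coding-potential model
#'
#' Runs the complete training flow: longest-ORF annotation, hexamer table
#' construction (coding ORFs vs noncoding transcript sequences), protein
#' document corpus and PV-DM embedding training, feature assembly for the
#' enabled groups, and the RBF-SVM fit with Platt calibration.
#'
#' When `test` transcripts are supplied, the embedding is trained
#' transductively on the joint train + test corpus (the protocol under
#' which stored vectors exist for the test set); without them, test-time
#' embeddings come from [embed_documents()] in `infer` mode.
#'
#' @param train A tibble with columns `id`, `seq`, `label`
#'   (`"coding"`/`"noncoding"`), e.g. from [read_transcripts()] joined with
#'   labels, or [simulate_transcripts()].
#' @param test Optional unlabeled tibble (`id`, `seq`) whose documents join
#'   the embedding corpus (transductive protocol).
#' @param feature_groups Subset of
#'   `c("orf", "protein", "rna", "ctd", "embedding")`. The default 10
#'   classic + 100 embedding features; `"embedding"` alone is the
#'   embedding-only ablation, dropping `"embedding"` the classic-only one.
#' @param dim,window,embed_epochs,min_count PV-DM parameters (see
#'   [train_pvdm()]).
#' @param C,gamma,scaling,threshold,calibration_folds SVM parameters (see
#'   [fit_coding_svm()]).
#' @param seed Seed for embedding training and calibration folds.
#' @return An object of class `orfvec_model` bundling the hexamer table,
#'   the PV-DM model, the fitted SVM and the configuration.
#' @export
orfvec_train <- function(train, test = NULL,
                         feature_groups = c("orf", "protein", "rna", "embedding"),
                         dim = 100L, window = 4L, embed_epochs = 20L,
                         min_count = 1L, C = 300, gamma = 0.4,
                         scaling = c("minmax_symmetric", "none"),
                         threshold = 0.5, calibration_folds = 3L, seed = 1L) {
  stopifnot(is.data.frame(train),
            all(c("id", "seq", "label") %in% names(train)))
  check_labels(train$label)
  feature_groups <- match.arg(feature_groups, FEATURE_GROUPS,
                              several.ok = TRUE)
  scaling <- match.arg(scaling)

  orfs <- find_orfs(train)

  hex_table <- NULL
  if ("orf" %in% feature_groups) {
    hex_table <- build_hexamer_table(
      coding_orfs = orfs$orf_seq[orfs$label == "coding"],
      noncoding_seqs = orfs$seq[orfs$label == "noncoding"])
  }

  pvdm <- NULL
  emb <- NULL
  if ("embedding" %in% feature_groups) {
    docs <- tibble(id = orfs$id, protein = orfs$protein)
    if (!is.null(test)) {
      test_orfs <- find_orfs(test)
      docs <- dplyr::bind_rows(docs, tibble(id = test_orfs$id,
                                            protein = test_orfs$protein))
    }
    corpus <- muffle_degenerate(build_corpus(docs))
    pvdm <- train_pvdm(corpus, dim = dim, window = window,
                       epochs = embed_epochs, min_count = min_count,
                       seed = seed)
    emb <- embed_documents(pvdm, orfs$id, mode = "stored")
  }

  features <- transcript_features(orfs, hex_table = hex_table,
                                  embeddings = emb, groups = feature_groups)
  features$label <- orfs$label
  svm <- fit_coding_svm(features, C = C, gamma = gamma, scaling = scaling,
                        threshold = threshold,
                        calibration_folds = calibration_folds, seed = seed)

  structure(
    list(svm = svm, hexamer_table = hex_table, pvdm = pvdm,
         feature_groups = feature_groups,
         config = list(dim = as.integer(dim), window = as.integer(window),
                       embed_epochs = as.integer(embed_epochs),
                       min_count = as.integer(min_count), C = C,
                       gamma = gamma, scaling = scaling,
                       threshold = threshold,
                       calibration_folds = as.integer(calibration_folds),
                       seed = as.integer(seed))),
    class = "orfvec_model")
}

#' Predict coding potential for transcripts
#'
#' @param model An `orfvec_model` from [orfvec_train()].
#' @param transcripts A tibble with `id` and `seq` columns.
#' @param embedding_mode `"stored"` looks the ids up among the model's
#'   trained paragraph vectors (the transductive protocol; ids must have
#'   been in the training corpus). `"infer"` optimizes fresh vectors with
#'   the word and softmax weights frozen, for transcripts unseen at
#'   training time.
#' @return A tibble with columns `id`, `label`, `coding_prob`,
#'   `decision_value`.
#' @export
orfvec_predict <- function(model, transcripts,
                           embedding_mode = c("stored", "infer")) {
  stopifnot(inherits(model, "orfvec_model"), is.data.frame(transcripts))
  embedding_mode <- match.arg(embedding_mode)
  orfs <- if (all(c("orf_seq", "protein") %in% names(transcripts))) {
    transcripts
  } else {
    find_orfs(transcripts)
  }
  emb <- NULL
  if ("embedding" %in% model$feature_groups) {
    emb <- if (embedding_mode == "stored") {
      embed_documents(model$pvdm, orfs$id, mode = "stored")
    } else {
      corpus <- muffle_degenerate(
        build_corpus(tibble(id = orfs$id, protein = orfs$protein)))
      muffle_degenerate(embed_documents(model$pvdm, corpus, mode = "infer"))
    }
  }
  features <- muffle_degenerate(
    transcript_features(orfs, hex_table = model$hexamer_table,
                        embeddings = emb, groups = model$feature_groups))
  stats::predict(model$svm, features)
}

#' Evaluate predictions against known labels
#'
#' @param predictions A predictions tibble from [orfvec_predict()].
#' @param labels A tibble with columns `id` and `label` holding the truth.
#' @return A one-row metrics tibble (see [classification_metrics()]).
#' @export
orfvec_evaluate <- function(predictions, labels) {
  stopifnot(all(c("id", "coding_prob") %in% names(predictions)),
            all(c("id", "label") %in% names(labels)))
  joined <- dplyr::inner_join(predictions, labels, by = "id",
                              suffix = c("_pred", ""))
  if (nrow(joined) == 0L) abort("No prediction ids match the labels.")
  classification_metrics(joined$label, joined$coding_prob)
}

#' @export
print.orfvec_model <- function(x, ...) {
  cat("Coding-potential model\n")
  cat("  feature groups:", paste(x$feature_groups, collapse = ", "), "\n")
  cat(sprintf("  features: %d; training samples: %d\n",
              length(x$svm$feature_names), x$svm$n_train))
  if (!is.null(x$pvdm)) {
    cat(sprintf("  embedding: PV-DM dim %d, window %d, %d epochs\n",
                x$pvdm$config$dim, x$pvdm$config$window,
                x$pvdm$config$epochs))
  }
  invisible(x)
}

#' Glance at a trained coding-potential model
#' @param x An `orfvec_model`.
#' @param ... Unused.
#' @return A one-row tibble of bundle summaries.
#' @export
glance.orfvec_model <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$svm),
    tibble(embedding_dim = if (is.null(x$pvdm)) NA_integer_ else x$pvdm$config$dim,
           feature_groups = paste(x$feature_groups, collapse = "+")))
}

#' Write predictions as TSV
#'
#' Columns `id`, `label`, `coding_prob`, probabilities printed to 6
#' decimals.
#'
#' @param predictions Predictions tibble from [orfvec_predict()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  out <- data.frame(id = predictions$id, label = predictions$label,
                    coding_prob = sprintf("%.6f", predictions$coding_prob))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persist a trained model bundle as plain text
#'
#' Writes the bundle into a directory: the hexamer table as TSV, the PV-DM
#' model as TSV matrices plus JSON manifest (see [save_pvdm()]), the
#' scaler, Platt coefficients and configuration as JSON, and the fitted
#' SVM's support-vector representation as [base::dput()] text.
#' [load_orfvec_model()] restores the bundle.
#'
#' @param model An `orfvec_model`.
#' @param dir Directory path.
#' @return `dir` (or the model for the loader), invisibly.
#' @export
save_orfvec_model <- function(model, dir) {
  stopifnot(inherits(model, "orfvec_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(model$hexamer_table)) {
    write_hexamer_table(model$hexamer_table, file.path(dir, "hexamer_table.tsv"))
  }
  if (!is.null(model$pvdm)) save_pvdm(model$pvdm, file.path(dir, "pvdm"))
  meta <- list(feature_groups = model$feature_groups, config = model$config,
               svm_config = model$svm$config,
               feature_names = model$svm$feature_names,
               scaler = model$svm$scaler, platt = model$svm$platt,
               format_version = 1L)
  jsonlite::write_json(meta, file.path(dir, "model_config.json"),
                       auto_unbox = TRUE, digits = NA)
  dput(model$svm$svm, file = file.path(dir, "svm.dput"), control = "exact")
  invisible(dir)
}

#' @rdname save_orfvec_model
#' @export
load_orfvec_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model_config.json"),
                              simplifyVector = TRUE)
  svm_fit <- dget(file.path(dir, "svm.dput"))
  scaler <- if (!is.null(meta$scaler)) {
    list(min = stats::setNames(as.numeric(meta$scaler$min), meta$feature_names),
         max = stats::setNames(as.numeric(meta$scaler$max), meta$feature_names))
  }
  svm <- structure(
    list(svm = svm_fit, scaler = scaler,
         platt = if (!is.null(meta$platt)) meta$platt,
         feature_names = meta$feature_names, config = meta$svm_config,
         n_train = svm_fit$tot.nSV %||% NA_integer_),
    class = "coding_svm")
  hex <- NULL
  hex_path <- file.path(dir, "hexamer_table.tsv")
  if (file.exists(hex_path)) hex <- read_hexamer_table(hex_path)
  pvdm <- NULL
  if (dir.exists(file.path(dir, "pvdm"))) {
    pvdm <- load_pvdm(file.path(dir, "pvdm"))
  }
  structure(list(svm = svm, hexamer_table = hex, pvdm = pvdm,
                 feature_groups = meta$feature_groups, config = meta$config),
            class = "orfvec_model")
}
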