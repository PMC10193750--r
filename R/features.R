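# Feature assembly: classic feature groups plus the paragraph-vector
# embedding, in a fixed, named column order.

#' GC content of a nucleotide sequence
#'
#' `(G + C) / length`; `N` characters count toward the length but not the
#' numerator.
#'
#' @param seq A normalized DNA string.
#' @return The GC fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  assert_scalar_string(seq, "seq")
  n <- nchar(seq)
  if (n < 1L) abort("`seq` must have length >= 1.")
  gc <- nchar(gsub("[^GC]", "", seq))
  gc / n
}

#' Basic ORF features
#'
#' ORF length in nucleotides, ORF coverage (length over transcript length)
#' and ORF integrity (+1 when both start and stop codon are present, -1
#' otherwise).
#'
#' @param orf An ORF record from [find_longest_orf()] (a list with `start`,
#'   `end`, `has_start`, `has_stop`).
#' @param transcript_len Transcript length in nucleotides (>= ORF length).
#' @return Named numeric vector `c(orf_length, orf_coverage, orf_integrity)`.
#' @export
orf_basic_features <- function(orf, transcript_len) {
  if (transcript_len == 0L) abort("`transcript_len` must be positive.")
  len <- orf$end - orf$start
  if (transcript_len < len) abort("`transcript_len` smaller than the ORF.")
  c(orf_length = as.numeric(len),
    orf_coverage = len / transcript_len,
    orf_integrity = if (orf$has_start && orf$has_stop) 1 else -1)
}

FEATURE_GROUPS <- c("orf", "protein", "rna", "ctd", "embedding")

#' Names of the classic features, by group
#' @param groups Subset of `c("orf", "protein", "rna", "ctd")`.
#' @return Character vector of feature (column) names in canonical order.
#' @export
classic_feature_names <- function(groups = c("orf", "protein", "rna")) {
  out <- character()
  if ("orf" %in% groups) {
    out <- c(out, "orf_length", "orf_coverage", "orf_integrity", "hexamer_score")
  }
  if ("protein" %in% groups) {
    out <- c(out, "protein_length", "isoelectric_point", "gravy",
             "instability_index")
  }
  if ("rna" %in% groups) out <- c(out, "fickett_score", "gc_content")
  if ("ctd" %in% groups) out <- c(out, names(ctd_features("ACGT")))
  out
}

#' Assemble the feature matrix for a set of transcripts
#'
#' Locates the longest ORF of every transcript (unless pre-annotated with
#' [find_orfs()]) and computes the enabled feature groups:
#' \describe{
#'   \item{orf}{`orf_length`, `orf_coverage`, `orf_integrity`, and the
#'     in-frame `hexamer_score` of the longest ORF (requires `hex_table`).}
#'   \item{protein}{`protein_length`, `isoelectric_point`, `gravy`,
#'     `instability_index` of the translated protein.}
#'   \item{rna}{`fickett_score` and `gc_content` of the full transcript.}
#'   \item{ctd}{the 30 composition/transition/distribution features
#'     (off by default).}
#'   \item{embedding}{the paragraph-vector columns, joined from
#'     `embeddings` by `id` (requires every id to be present).}
#' }
#' The default groups (`orf`, `protein`, `rna`, `embedding` with a
#' 100-dimensional embedding) yield 110 features per transcript. Warnings
#' from degenerate proteins (empty, single-residue) are suppressed here;
#' the features fall back to their documented 0 defaults.
#'
#' @param transcripts Tibble with `id` and `seq` columns; ORF columns from
#'   [find_orfs()] are reused when present.
#' @param hex_table Hexamer table from [build_hexamer_table()]; required
#'   when the `orf` group is enabled.
#' @param embeddings Tibble of document vectors (`id` + numeric columns), as
#'   returned by [embed_documents()]; required when the `embedding` group is
#'   enabled.
#' @param groups Character subset of
#'   `c("orf", "protein", "rna", "ctd", "embedding")`.
#' @return A tibble: `id` column plus one numeric column per feature, in
#'   canonical order.
#' @export
transcript_features <- function(transcripts, hex_table = NULL,
                                embeddings = NULL,
                                groups = c("orf", "protein", "rna", "embedding")) {
  stopifnot(is.data.frame(transcripts))
  groups <- match.arg(groups, FEATURE_GROUPS, several.ok = TRUE)
  if (!all(c("orf_seq", "protein") %in% names(transcripts))) {
    transcripts <- find_orfs(transcripts)
  }
  out <- tibble(id = transcripts$id)

  if ("orf" %in% groups) {
    if (is.null(hex_table)) {
      abort("Feature group 'orf' requires `hex_table`.")
    }
    validate_hexamer_table(hex_table)
    len <- transcripts$orf_end - transcripts$orf_start
    out$orf_length <- as.numeric(len)
    out$orf_coverage <- len / nchar(transcripts$seq)
    out$orf_integrity <- ifelse(transcripts$has_start & transcripts$has_stop, 1, -1)
    out$hexamer_score <- hexamer_score_many(transcripts$orf_seq, hex_table)
  }
  if ("protein" %in% groups) {
    out$protein_length <- as.numeric(nchar(transcripts$protein))
    suppressWarnings({
      out$isoelectric_point <- vapply(transcripts$protein, isoelectric_point,
                                      numeric(1), USE.NAMES = FALSE)
      out$gravy <- vapply(transcripts$protein, gravy, numeric(1),
                          USE.NAMES = FALSE)
      out$instability_index <- vapply(transcripts$protein, instability_index,
                                      numeric(1), USE.NAMES = FALSE)
    })
  }
  if ("rna" %in% groups) {
    out$fickett_score <- vapply(transcripts$seq, fickett_score, numeric(1),
                                USE.NAMES = FALSE)
    out$gc_content <- vapply(transcripts$seq, gc_content, numeric(1),
                             USE.NAMES = FALSE)
  }
  if ("ctd" %in% groups) {
    ctd <- t(vapply(transcripts$seq, ctd_features, numeric(30L),
                    USE.NAMES = FALSE))
    colnames(ctd) <- names(ctd_features("ACGT"))
    out <- dplyr::bind_cols(out, as_tibble(ctd))
  }
  if ("embedding" %in% groups) {
    if (is.null(embeddings)) {
      abort("Feature group 'embedding' requires `embeddings`.")
    }
    missing_ids <- setdiff(out$id, embeddings$id)
    if (length(missing_ids) > 0L) {
      abort(sprintf("No embedding for transcript id(s): %s",
                    paste(utils::head(missing_ids, 5L), collapse = ", ")))
    }
    out <- dplyr::left_join(out, embeddings, by = "id")
  }

  bad <- !vapply(out[-1L], function(x) all(is.finite(x)), logical(1))
  if (any(bad)) {
    abort(sprintf("Non-finite feature value(s) in: %s",
                  paste(names(out[-1L])[bad], collapse = ", ")))
  }
  out
}

#' Write / read a feature matrix as TSV
#'
#' Header row of feature names; first column is the transcript id.
#'
#' @param features Feature tibble from [transcript_features()].
#' @param path File path.
#' @return `write_feature_tsv()` returns `path` invisibly;
#'   `read_feature_tsv()` returns the tibble.
#' @export
write_feature_tsv <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                              check.names = FALSE))
}
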