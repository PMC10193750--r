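#' Read transcript sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file of transcript
#' sequences and normalizes each sequence to the internal DNA alphabet:
#' upper case, `U` converted to `T`, and every other IUPAC ambiguity code
#' (`R`, `Y`, `S`, `W`, `K`, `M`, `B`, `D`, `H`, `V`) converted to `N`.
#' Characters outside the IUPAC nucleotide alphabet are an error.
#'
#' @param path Path to a FASTA file. The record identifier is the first
#'   whitespace-delimited token of the header line; duplicate identifiers are
#'   rejected.
#' @return A tibble with one row per record, in file order, and columns
#'   `id` (character), `seq` (normalized DNA string over `A,C,G,T,N`) and
#'   `length` (sequence length in nucleotides).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1 some description", "augcATGAAATAG", ">tx2", "acgr"), fa)
#' read_transcripts(fa)
#' @export
read_transcripts <- function(path) {
  assert_scalar_string(path, "path")
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: '%s'", path))
  }
  if (file.size(path) == 0L) {
    return(tibble(id = character(), seq = character(), length = integer()))
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(trimws(first), ">")) {
    abort(sprintf("Malformed FASTA '%s': sequence data before first header.", path))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate FASTA identifiers: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) {
    normalize_dna(seqs[[i]], id = ids[[i]])
  }, character(1))
  tibble(id = ids, seq = unname(seqs), length = nchar(seqs))
}

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Upper-cases the input, converts `U` to `T` and the remaining IUPAC
#' ambiguity codes to `N`. Any character outside the IUPAC nucleotide
#' alphabet raises a validation error naming the offending record.
#'
#' @param seq A nucleotide string.
#' @param id Optional record identifier used in error messages.
#' @return The normalized string over `A,C,G,T,N`.
#' @export
normalize_dna <- function(seq, id = NULL) {
  assert_scalar_string(seq, "seq")
  s <- toupper(seq)
  s <- chartr("U", "T", s)
  # remaining IUPAC ambiguity codes collapse to N
  s <- chartr("RYSWKMBDHV", strrep("N", 10L), s)
  bad <- gsub("[ACGTN]", "", s)
  if (nchar(bad) > 0L) {
    who <- if (is.null(id)) "sequence" else sprintf("record '%s'", id)
    abort(sprintf("Invalid nucleotide character(s) '%s' in %s.",
                  paste(unique(strsplit(bad, "")[[1]]), collapse = ""), who))
  }
  s
}

#' Write transcripts to a FASTA file
#'
#' Emits standard FASTA with sequence lines wrapped at 60 columns.
#'
#' @param transcripts A data frame with columns `id` and `seq`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  stopifnot(is.data.frame(transcripts), all(c("id", "seq") %in% names(transcripts)))
  set <- Biostrings::BStringSet(transcripts$seq)
  names(set) <- transcripts$id
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
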