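STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Locate the longest open reading frame of a transcript
#'
#' Scans the three forward reading frames (transcripts are single-stranded;
#' no reverse-complement search) for complete ORFs -- `ATG` through the first
#' in-frame stop codon, stop included -- and returns the longest. Ties are
#' broken by smallest start coordinate, then smallest frame.
#'
#' When no complete ORF exists the function falls back to (1) the longest
#' `ATG`-to-sequence-end stretch with no in-frame stop, trimmed to a whole
#' number of codons (`has_stop = FALSE`); or, if the sequence contains no
#' `ATG` at all, (2) the full sequence in frame 0
#' (`has_start = has_stop = FALSE`). Every transcript therefore yields an
#' ORF record whose completeness flags feed the ORF-integrity feature.
#'
#' @param seq A normalized DNA string (see [normalize_dna()]).
#' @return A list with elements `start` (0-based inclusive), `end` (0-based
#'   exclusive), `frame` (0, 1 or 2), `nt_seq`, `has_start`, `has_stop`, and
#'   `protein` (translation of `nt_seq`, stop excluded).
#' @examples
#' find_longest_orf("ATGAAATAG")
#' @export
find_longest_orf <- function(seq) {
  assert_scalar_string(seq, "seq")
  n <- nchar(seq)
  if (n < 1L) abort("`seq` must have length >= 1.")

  best <- NULL # c(len_nt, start0, frame)
  fallback <- NULL # best ATG-to-end stretch: c(len_nt, start0, frame)
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    first_nt <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(seq, first_nt, first_nt + 2L)
    atg <- which(codons == "ATG")
    if (length(atg) == 0L) next
    stops <- which(codons %in% STOP_CODONS)
    if (length(stops) > 0L) {
      # index of first stop at or after each ATG codon
      nxt <- findInterval(atg - 1L, stops) + 1L
      ok <- nxt <= length(stops)
      if (any(ok)) {
        a <- atg[ok]
        s <- stops[nxt[ok]]
        len <- (s - a + 1L) * 3L
        i <- order(-len, a)[1L]
        cand <- c(len[i], frame + 3L * (a[i] - 1L), frame)
        if (is.null(best) ||
            cand[1L] > best[1L] ||
            (cand[1L] == best[1L] && cand[2L] < best[2L])) {
          best <- cand
        }
      }
      open_atg <- atg[findInterval(atg - 1L, stops) == length(stops)]
    } else {
      open_atg <- atg
    }
    # stop-free ATG-to-end stretches, for the fallback ladder
    if (length(open_atg) > 0L) {
      a <- open_atg[1L]
      len <- (ncod - a + 1L) * 3L
      cand <- c(len, frame + 3L * (a - 1L), frame)
      if (is.null(fallback) ||
          cand[1L] > fallback[1L] ||
          (cand[1L] == fallback[1L] && cand[2L] < fallback[2L])) {
        fallback <- cand
      }
    }
  }

  if (!is.null(best)) {
    start <- best[2L]
    end <- start + best[1L]
    has_start <- TRUE
    has_stop <- TRUE
    frame <- best[3L]
  } else if (!is.null(fallback)) {
    start <- fallback[2L]
    end <- start + fallback[1L]
    has_start <- TRUE
    has_stop <- FALSE
    frame <- fallback[3L]
  } else {
    start <- 0L
    end <- n
    has_start <- FALSE
    has_stop <- FALSE
    frame <- 0L
  }
  nt_seq <- substr(seq, start + 1L, end)
  list(start = as.integer(start), end = as.integer(end),
       frame = as.integer(frame), nt_seq = nt_seq,
       has_start = has_start, has_stop = has_stop,
       protein = translate_cds(nt_seq))
}

#' Translate a coding sequence with the standard genetic code
#'
#' Codons are read from position 0 in steps of 3. Translation stops at (and
#' excludes) the first stop codon; codons containing `N` translate to `X`;
#' a trailing partial codon is ignored. Inputs shorter than 3 nt give an
#' empty protein.
#'
#' @param nt_seq A normalized DNA string.
#' @return The amino-acid string.
#' @examples
#' translate_cds("ATGGCTTAA")
#' @export
translate_cds <- function(nt_seq) {
  assert_scalar_string(nt_seq, "nt_seq")
  n <- nchar(nt_seq)
  if (n < 3L) return("")
  ncod <- n %/% 3L
  first_nt <- 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(nt_seq, first_nt, first_nt + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  paste(aa, collapse = "")
}

#' Annotate transcripts with their longest ORF
#'
#' Applies [find_longest_orf()] to every row of a transcript table and binds
#' the result as new columns, so downstream feature extraction can share one
#' ORF scan.
#'
#' @param transcripts A tibble with columns `id` and `seq`
#'   (as from [read_transcripts()]).
#' @return The input tibble with added columns `orf_start`, `orf_end`,
#'   `orf_frame`, `orf_seq`, `has_start`, `has_stop` and `protein`.
#' @export
find_orfs <- function(transcripts) {
  stopifnot(is.data.frame(transcripts), all(c("id", "seq") %in% names(transcripts)))
  orfs <- purrr::map(transcripts$seq, find_longest_orf)
  dplyr::mutate(as_tibble(transcripts),
    orf_start = purrr::map_int(orfs, "start"),
    orf_end = purrr::map_int(orfs, "end"),
    orf_frame = purrr::map_int(orfs, "frame"),
    orf_seq = purrr::map_chr(orfs, "nt_seq"),
    has_start = purrr::map_lgl(orfs, "has_start"),
    has_stop = purrr::map_lgl(orfs, "has_stop"),
    protein = purrr::map_chr(orfs, "protein")
  )
}
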