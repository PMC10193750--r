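# In-frame hexamer usage table and log-likelihood score.
#
# The hexamer score is computed on the first reading frame of the longest
# ORF: hexamers are read from position 0 in steps of 3 (i.e. codon pairs),
# so the table must be built the same way.

#' All 4096 DNA hexamers in lexicographic order
#' @return Character vector of length 4096.
#' @export
all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(do.call(paste0, g))
}

# hexamers of `seq` read from position 0 in steps of 3, N-containing skipped
inframe_hexamers <- function(seq) {
  n <- nchar(seq)
  if (n < 6L) return(character())
  starts <- seq.int(1L, n - 5L, by = 3L)
  h <- substring(seq, starts, starts + 5L)
  h[!grepl("N", h, fixed = TRUE)]
}

#' Build per-class hexamer frequency tables
#'
#' Counts in-frame hexamers (position 0, step 3) of the coding ORFs and of
#' the noncoding sequences, and normalizes each class to frequencies.
#' Hexamers containing `N` are skipped; sequences shorter than 6 nt
#' contribute nothing.
#'
#' @param coding_orfs Character vector of coding ORF nucleotide sequences
#'   (each starting at the ORF's first codon).
#' @param noncoding_seqs Character vector of noncoding transcript sequences.
#' @return A tibble with columns `hexamer` (all 4096 hexamers), `coding_freq`
#'   and `noncoding_freq`, each class summing to 1 when any hexamer was
#'   counted.
#' @export
build_hexamer_table <- function(coding_orfs, noncoding_seqs) {
  if (length(coding_orfs) == 0L || length(noncoding_seqs) == 0L) {
    abort("Both `coding_orfs` and `noncoding_seqs` must be non-empty.")
  }
  hex <- all_hexamers()
  count_class <- function(seqs) {
    h <- unlist(lapply(seqs, inframe_hexamers), use.names = FALSE)
    cnt <- tabulate(factor(h, levels = hex), nbins = length(hex))
    tot <- sum(cnt)
    if (tot > 0L) cnt / tot else rep(0, length(hex))
  }
  tibble(hexamer = hex,
         coding_freq = count_class(coding_orfs),
         noncoding_freq = count_class(noncoding_seqs))
}

# per-hexamer log-ratio with the zero-frequency fallbacks:
# both 0 -> 0; coding 0 -> -1; noncoding 0 -> +1
hexamer_log_ratios <- function(table) {
  c <- table$coding_freq
  n <- table$noncoding_freq
  r <- numeric(length(c))
  both <- c > 0 & n > 0
  r[both] <- log(c[both] / n[both])
  r[c == 0 & n > 0] <- -1
  r[c > 0 & n == 0] <- 1
  names(r) <- table$hexamer
  r
}

#' In-frame hexamer log-likelihood score
#'
#' Reads hexamers from position 0 of `orf_seq` in steps of 3 (skipping
#' hexamers that contain `N`) and averages the per-hexamer log-ratio
#' `log(coding_freq / noncoding_freq)`. Zero frequencies fall back to 0
#' (both absent), -1 (absent from coding) or +1 (absent from noncoding).
#' Sequences yielding no hexamer score 0.
#'
#' @param orf_seq The longest-ORF nucleotide sequence (or any sequence whose
#'   position 0 is the reading frame to score).
#' @param table A hexamer frequency table from [build_hexamer_table()].
#' @return The mean log-ratio (a single number).
#' @export
hexamer_score <- function(orf_seq, table) {
  validate_hexamer_table(table)
  hexamer_score_many(orf_seq, table)[[1L]]
}

# vectorized over sequences; shares the precomputed log-ratio lookup
hexamer_score_many <- function(seqs, table) {
  r <- hexamer_log_ratios(table)
  vapply(seqs, function(s) {
    h <- inframe_hexamers(s)
    if (length(h) == 0L) return(0)
    mean(r[h])
  }, numeric(1), USE.NAMES = FALSE)
}

validate_hexamer_table <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("hexamer", "coding_freq", "noncoding_freq") %in% names(table)) ||
      nrow(table) != 4096L) {
    abort("`table` must be a 4096-row hexamer table from build_hexamer_table().")
  }
  invisible(table)
}

#' Read / write a hexamer table as TSV
#'
#' Three tab-separated columns: `hexamer`, `coding_freq`, `noncoding_freq`.
#'
#' @param table A hexamer table tibble.
#' @param path File path.
#' @return `write_hexamer_table()` returns `path` invisibly;
#'   `read_hexamer_table()` returns the table tibble.
#' @export
write_hexamer_table <- function(table, path) {
  validate_hexamer_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hexamer_table
#' @export
read_hexamer_table <- function(path) {
  tab <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  tab <- tab[order(tab$hexamer), ]
  validate_hexamer_table(tab)
  tab
}
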