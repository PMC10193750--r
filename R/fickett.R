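# Fickett TESTCODE statistic, computed from the published lookup tables
# shipped in inst/extdata/fickett_testcode.tsv.

fickett_tables <- function() {
  if (is.null(the$fickett)) {
    tab <- extdata_table("fickett_testcode.tsv")
    split_tab <- split(tab, interaction(tab$kind, tab$base, drop = TRUE))
    the$fickett <- split_tab
  }
  the$fickett
}

fickett_lookup <- function(value, kind, base) {
  tab <- fickett_tables()[[paste(kind, base, sep = ".")]]
  # first row (top-down) whose threshold the value reaches
  idx <- which(value >= tab$threshold)[1L]
  tab$probability[idx] * tab$weight[idx]
}

#' Fickett TESTCODE score of a nucleotide sequence
#'
#' The classic TESTCODE statistic: for each base, a codon-position asymmetry
#' parameter (the maximum of the base's counts in the three codon positions
#' divided by the minimum plus one) and a content parameter (the base's
#' fraction of the sequence) are mapped through the published probability
#' tables and combined with the published weights. `N` characters contribute
#' to no base count (the sequence length still includes them).
#'
#' @param seq A normalized DNA string.
#' @return The TESTCODE score (a single number).
#' @export
fickett_score <- function(seq) {
  assert_scalar_string(seq, "seq")
  n <- nchar(seq)
  if (n < 1L) abort("`seq` must have length >= 1.")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  score <- 0
  pos_of <- (seq_len(n) - 1L) %% 3L # codon position 0/1/2
  for (b in bases) {
    hits <- chars == b
    pos_counts <- tabulate(pos_of[hits] + 1L, nbins = 3L)
    position_par <- max(pos_counts) / (min(pos_counts) + 1)
    content_par <- sum(hits) / n
    score <- score +
      fickett_lookup(position_par, "position", b) +
      fickett_lookup(content_par, "content", b)
  }
  score
}
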