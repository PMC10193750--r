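#' Composition / transition / distribution (CTD) features
#'
#' Thirty summary statistics of a nucleotide sequence:
#' \itemize{
#'   \item 4 composition features: the fraction of each base (`N` counts
#'     toward the length but no base).
#'   \item 6 transition features: for each unordered base pair, the fraction
#'     of adjacent positions holding that (unequal) pair, out of all
#'     `length - 1` adjacent pairs.
#'   \item 20 distribution features: for each base, the 1-based position of
#'     its 1st, 25th-percentile, 50th-percentile, 75th-percentile and last
#'     occurrence (occurrence index `ceiling(q * count)`), divided by the
#'     sequence length; all five are 0 when the base is absent.
#' }
#'
#' @param seq A normalized DNA string.
#' @return A named numeric vector of length 30, in the order composition
#'   (`comp_A..comp_T`), transitions (`trans_AC..trans_GT`), distributions
#'   (`dist_A_p0 .. dist_T_p100`).
#' @export
ctd_features <- function(seq) {
  assert_scalar_string(seq, "seq")
  n <- nchar(seq)
  if (n < 1L) abort("`seq` must have length >= 1.")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")

  comp <- vapply(bases, function(b) sum(chars == b) / n, numeric(1))
  names(comp) <- paste0("comp_", bases)

  pairs <- utils::combn(bases, 2L)
  if (n >= 2L) {
    a <- chars[-n]
    b <- chars[-1L]
    trans <- apply(pairs, 2L, function(p) {
      sum((a == p[1L] & b == p[2L]) | (a == p[2L] & b == p[1L])) / (n - 1L)
    })
  } else {
    trans <- rep(0, 6L)
  }
  names(trans) <- paste0("trans_", pairs[1L, ], pairs[2L, ])

  qs <- c(0, 0.25, 0.5, 0.75, 1)
  dist <- unlist(lapply(bases, function(bb) {
    pos <- which(chars == bb)
    cnt <- length(pos)
    if (cnt == 0L) return(rep(0, 5L))
    idx <- pmax(1L, ceiling(qs * cnt))
    pos[idx] / n
  }))
  names(dist) <- paste0("dist_", rep(bases, each = 5L), "_p",
                        rep(c(0, 25, 50, 75, 100), times = 4L))

  c(comp, trans, dist)
}
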