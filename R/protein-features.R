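# Physicochemical properties of the translated protein: GRAVY (Kyte &
# Doolittle hydropathy), isoelectric point (EMBOSS pKa set), and the
# Guruprasad instability index. Constant tables ship in inst/extdata.

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

kd_table <- function() {
  if (is.null(the$kd)) {
    tab <- extdata_table("kyte_doolittle_hydropathy.tsv")
    the$kd <- stats::setNames(tab$hydropathy, tab$residue)
  }
  the$kd
}

diwv_matrix <- function() {
  if (is.null(the$diwv)) {
    tab <- extdata_table("instability_diwv.tsv")
    m <- as.matrix(tab[, -1L])
    rownames(m) <- tab$residue
    colnames(m) <- tab$residue # columns are written in residue order
    the$diwv <- m
  }
  the$diwv
}

pka_table <- function() {
  if (is.null(the$pka)) the$pka <- extdata_table("pka_emboss.tsv")
  the$pka
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the standard residues of a protein.
#' `X` (unknown) residues are excluded from both numerator and denominator.
#' An empty or all-`X` protein returns 0 with a warning.
#'
#' @param protein An amino-acid string.
#' @return The mean hydropathy (a single number).
#' @export
gravy <- function(protein) {
  assert_scalar_string(protein, "protein")
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  h <- kd_table()[chars]
  h <- h[!is.na(h)]
  if (length(h) == 0L) {
    warn("GRAVY of an empty or all-unknown protein; returning 0.",
         class = "orfvec_degenerate_input")
    return(0)
  }
  mean(h)
}

# net charge of the protein at a given pH (Henderson-Hasselbalch)
protein_charge <- function(counts, pH) {
  tab <- pka_table()
  chg <- 0
  for (i in seq_len(nrow(tab))) {
    n <- counts[[tab$group[i]]]
    if (is.null(n) || n == 0) next
    if (tab$sign[i] > 0) {
      chg <- chg + n / (1 + 10^(pH - tab$pka[i]))
    } else {
      chg <- chg - n / (1 + 10^(tab$pka[i] - pH))
    }
  }
  chg
}

#' Isoelectric point of a protein
#'
#' The pH in `[0, 14]` at which the Henderson-Hasselbalch net charge of the
#' protein (free N- and C-termini plus the ionizable side chains C, D, E, H,
#' K, R, Y under the packaged EMBOSS pKa set) is zero, found by bisection to
#' `|charge| < 1e-4`. `X` residues carry no side-chain charge. An empty
#' protein has no ionizable group and returns 0 with a warning.
#'
#' @param protein An amino-acid string.
#' @return The isoelectric pH (a single number).
#' @export
isoelectric_point <- function(protein) {
  assert_scalar_string(protein, "protein")
  if (nchar(protein) == 0L) {
    warn("Isoelectric point of an empty protein; returning 0.",
         class = "orfvec_degenerate_input")
    return(0)
  }
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  counts <- as.list(table(factor(chars, levels = AA_STANDARD)))
  counts$nterm <- 1L
  counts$cterm <- 1L
  lo <- 0
  hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    chg <- protein_charge(counts, mid)
    if (abs(chg) < 1e-4) break
    if (chg > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Guruprasad instability index
#'
#' `(10 / L) * sum(DIWV(x_i, x_(i+1)))` over the `L - 1` dipeptides of the
#' protein, using the packaged published dipeptide weight table. Dipeptides
#' containing `X` contribute the table's default weight (0). Proteins
#' shorter than 2 residues return 0 with a warning.
#'
#' @param protein An amino-acid string.
#' @return The instability index (a single number).
#' @export
instability_index <- function(protein) {
  assert_scalar_string(protein, "protein")
  L <- nchar(protein)
  if (L < 2L) {
    warn("Instability index of a protein shorter than 2 residues; returning 0.",
         class = "orfvec_degenerate_input")
    return(0)
  }
  m <- diwv_matrix()
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  i1 <- match(chars[-L], rownames(m))
  i2 <- match(chars[-1L], colnames(m))
  w <- ifelse(is.na(i1) | is.na(i2), 0, m[cbind(i1, i2)])
  (10 / L) * sum(w, na.rm = TRUE)
}
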