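# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive everything from first principles with naive
# loops, sharing no code with the package internals.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

oracle_stops <- c("TAA", "TAG", "TGA")

# enumerate every ATG..first-in-frame-stop span in all 3 frames; return the
# longest (ties: smallest start), replicating the fallback ladder when no
# complete ORF exists. Returns list(start, end, frame) in 0-based half-open.
orf_oracle <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (fr in 0:2) {
    i <- fr + 1L
    while (i + 2L <= n) {
      if (substr(seq, i, i + 2L) == "ATG") {
        j <- i
        found <- FALSE
        while (j + 2L <= n) {
          if (substr(seq, j, j + 2L) %in% oracle_stops) {
            found <- TRUE
            break
          }
          j <- j + 3L
        }
        if (found) {
          len <- j + 3L - i
          if (is.null(best) || len > best$len ||
              (len == best$len && i - 1L < best$start)) {
            best <- list(len = len, start = i - 1L, frame = fr)
          }
        }
      }
      i <- i + 3L
    }
  }
  if (!is.null(best)) {
    return(list(start = best$start, end = best$start + best$len, frame = best$frame,
                has_start = TRUE, has_stop = TRUE))
  }
  # fallback 1: longest stop-free ATG-to-end stretch, whole codons
  for (fr in 0:2) {
    i <- fr + 1L
    while (i + 2L <= n) {
      if (substr(seq, i, i + 2L) == "ATG") {
        j <- i
        clean <- TRUE
        while (j + 2L <= n) {
          if (substr(seq, j, j + 2L) %in% oracle_stops) {
            clean <- FALSE
            break
          }
          j <- j + 3L
        }
        if (clean) {
          len <- 3L * ((n - i + 1L) %/% 3L)
          if (is.null(best) || len > best$len ||
              (len == best$len && i - 1L < best$start)) {
            best <- list(len = len, start = i - 1L, frame = fr)
          }
        }
      }
      i <- i + 3L
    }
  }
  if (!is.null(best)) {
    return(list(start = best$start, end = best$start + best$len, frame = best$frame,
                has_start = TRUE, has_stop = FALSE))
  }
  list(start = 0L, end = n, frame = 0L, has_start = FALSE, has_stop = FALSE)
}

# naive in-frame hexamer log-ratio score straight from the definition
naive_hexamer_score <- function(orf_seq, table) {
  cod <- setNames(table$coding_freq, table$hexamer)
  nc <- setNames(table$noncoding_freq, table$hexamer)
  total <- 0
  m <- 0
  i <- 1L
  while (i + 5L <= nchar(orf_seq)) {
    h <- substr(orf_seq, i, i + 5L)
    if (!grepl("N", h)) {
      c1 <- cod[[h]]
      n1 <- nc[[h]]
      r <- if (c1 == 0 && n1 == 0) 0
      else if (c1 == 0) -1
      else if (n1 == 0) 1
      else log(c1 / n1)
      total <- total + r
      m <- m + 1L
    }
    i <- i + 3L
  }
  if (m == 0L) 0 else total / m
}

naive_ctd <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  bases <- c("A", "C", "G", "T")
  comp <- sapply(bases, function(b) sum(chars == b) / n)
  pairs <- list(c("A","C"), c("A","G"), c("A","T"), c("C","G"), c("C","T"), c("G","T"))
  trans <- sapply(pairs, function(p) {
    cnt <- 0
    for (i in seq_len(n - 1L)) {
      if ((chars[i] == p[1] && chars[i+1] == p[2]) ||
          (chars[i] == p[2] && chars[i+1] == p[1])) cnt <- cnt + 1
    }
    cnt / (n - 1L)
  })
  dist <- c()
  for (b in bases) {
    pos <- which(chars == b)
    if (length(pos) == 0) {
      dist <- c(dist, rep(0, 5))
    } else {
      for (q in c(0, 0.25, 0.5, 0.75, 1)) {
        k <- max(1, ceiling(q * length(pos)))
        dist <- c(dist, pos[k] / n)
      }
    }
  }
  unname(c(comp, trans, dist))
}

read_pkg_table <- function(name) {
  utils::read.delim(system.file("extdata", name, package = "orfvec"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

naive_gravy <- function(protein) {
  tab <- read_pkg_table("kyte_doolittle_hydropathy.tsv")
  kd <- setNames(tab$hydropathy, tab$residue)
  vals <- kd[strsplit(protein, "")[[1]]]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) 0 else sum(vals) / length(vals)
}

naive_instability <- function(protein) {
  tab <- read_pkg_table("instability_diwv.tsv")
  m <- as.matrix(tab[, -1]); rownames(m) <- tab$residue; colnames(m) <- tab$residue
  chars <- strsplit(protein, "")[[1]]
  L <- length(chars)
  s <- 0
  for (i in seq_len(L - 1)) {
    a <- chars[i]; b <- chars[i + 1]
    if (a %in% rownames(m) && b %in% colnames(m)) s <- s + m[a, b]
  }
  10 / L * s
}

naive_pi <- function(protein) {
  tab <- read_pkg_table("pka_emboss.tsv")
  chars <- strsplit(protein, "")[[1]]
  charge <- function(pH) {
    tot <- 0
    for (i in seq_len(nrow(tab))) {
      n <- if (tab$group[i] %in% c("nterm", "cterm")) 1 else sum(chars == tab$group[i])
      if (n == 0) next
      tot <- tot + if (tab$sign[i] > 0) n / (1 + 10^(pH - tab$pka[i]))
      else -n / (1 + 10^(tab$pka[i] - pH))
    }
    tot
  }
  uniroot(charge, c(0, 14), tol = 1e-10)$root
}

# second independent TESTCODE implementation
naive_fickett <- function(seq) {
  tab <- read_pkg_table("fickett_testcode.tsv")
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  score <- 0
  codon_pos <- (seq_len(n) - 1L) %% 3L
  for (b in c("A", "C", "G", "T")) {
    cnt <- sapply(0:2, function(k) sum(chars == b & codon_pos == k))
    posval <- max(cnt) / (min(cnt) + 1)
    contval <- sum(chars == b) / n
    for (kind in c("position", "content")) {
      sub <- tab[tab$kind == kind & tab$base == b, ]
      v <- if (kind == "position") posval else contval
      row <- sub[which(v >= sub$threshold)[1], ]
      score <- score + row$probability * row$weight
    }
  }
  score
}

naive_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) 0 else a / b
  sn <- div(tp, tp + fn)
  sp <- div(tn, fp + tn)
  pre <- div(tp, tp + fp)
  acc <- div(tp + tn, tp + fp + tn + fn)
  f <- div(2 * pre * sn, pre + sn)
  den <- sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  c(SN = sn, SP = sp, PRE = pre, ACC = acc, F_score = f, MCC = mcc)
}

# Mann-Whitney / rank-sum formulation of the AUC with average ranks for ties
auc_rank_sum <- function(truth, scores) {
  r <- rank(scores)
  npos <- sum(truth == "coding")
  nneg <- sum(truth == "noncoding")
  (sum(r[truth == "coding"]) - npos * (npos + 1) / 2) / (npos * nneg)
}
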