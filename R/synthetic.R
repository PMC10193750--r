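# Seeded synthetic transcript simulator. Coding transcripts are
# 5'UTR + codon-biased ORF (ATG ... stop) + 3'UTR; noncoding transcripts
# are mononucleotide-composition-matched random sequences with no long ORF
# (rejection-sampled), optionally carrying a planted short ORF or, in
# hard-negative mode, indel-corrupted coding-like templates.

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

#' Configuration for the synthetic transcript simulator
#'
#' @param n_coding,n_noncoding Number of records per class.
#' @param len_range Total transcript length range in nt (min >= 60).
#' @param utr5_range,utr3_range UTR length ranges in nt.
#' @param codon_bias_concentration Symmetric Dirichlet concentration for the
#'   dataset's codon-usage distribution over the 61 sense codons; smaller
#'   values give a more skewed (more mRNA-like) usage.
#' @param max_nc_orf Reject noncoding sequences whose longest ORF exceeds
#'   this many nt.
#' @param sorf_prob Probability that a noncoding sequence carries a planted
#'   short ORF of 30-150 nt (emulating micropeptide-bearing lncRNAs).
#' @param indel_rate Per-nt indel probability; when positive, noncoding
#'   sequences are indel-corrupted coding-like templates (hard negatives)
#'   instead of composition-matched random sequences.
#' @param seed Integer seed; the same config yields byte-identical output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_coding = 1000L, n_noncoding = 1000L,
                             len_range = c(200L, 3000L),
                             utr5_range = c(10L, 300L),
                             utr3_range = c(10L, 300L),
                             codon_bias_concentration = 0.5,
                             max_nc_orf = 300L, sorf_prob = 0.25,
                             indel_rate = 0, seed = 42L) {
  if (n_coding < 0L || n_noncoding < 0L) abort("Record counts must be >= 0.")
  if (sorf_prob < 0 || sorf_prob > 1 || indel_rate < 0 || indel_rate > 1) {
    abort("`sorf_prob` and `indel_rate` must be probabilities in [0, 1].")
  }
  if (len_range[1L] < 60L) abort("`len_range` minimum must be >= 60 nt.")
  if (len_range[1L] < utr5_range[1L] + utr3_range[1L] + 90L) {
    abort("Infeasible lengths: len_range minimum cannot hold the minimal UTRs plus a 90-nt ORF.")
  }
  if (codon_bias_concentration <= 0) {
    abort("`codon_bias_concentration` must be positive.")
  }
  structure(list(n_coding = as.integer(n_coding),
                 n_noncoding = as.integer(n_noncoding),
                 len_range = as.integer(len_range),
                 utr5_range = as.integer(utr5_range),
                 utr3_range = as.integer(utr3_range),
                 codon_bias_concentration = codon_bias_concentration,
                 max_nc_orf = as.integer(max_nc_orf),
                 sorf_prob = sorf_prob, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

rand_bases <- function(n, probs) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# dataset-level codon usage: one draw from a symmetric Dirichlet
draw_codon_probs <- function(concentration) {
  g <- stats::rgamma(length(SENSE_CODONS), shape = concentration)
  stats::setNames(g / sum(g), SENSE_CODONS)
}

# mononucleotide composition implied by a codon distribution
codon_base_probs <- function(codon_probs) {
  m <- do.call(rbind, strsplit(names(codon_probs), ""))
  p <- vapply(c("A", "C", "G", "T"), function(b) {
    sum(codon_probs * rowSums(m == b)) / 3
  }, numeric(1))
  p / sum(p)
}

simulate_coding_one <- function(config, codon_probs, base_probs, id) {
  len <- sample(config$len_range[1L]:config$len_range[2L], 1L)
  u5_max <- min(config$utr5_range[2L], len - config$utr3_range[1L] - 90L)
  u5 <- sample(config$utr5_range[1L]:u5_max, 1L)
  u3_max <- min(config$utr3_range[2L], len - u5 - 90L)
  u3 <- sample(config$utr3_range[1L]:u3_max, 1L)
  orf_len <- len - u5 - u3
  u3 <- u3 + orf_len %% 3L # keep the ORF a whole number of codons
  orf_len <- orf_len - orf_len %% 3L
  ncod <- orf_len %/% 3L
  orf <- paste0("ATG",
                paste(sample(SENSE_CODONS, ncod - 2L, replace = TRUE,
                             prob = codon_probs), collapse = ""),
                sample(STOP_CODONS, 1L))
  for (attempt in 1:1000) {
    seq <- paste0(rand_bases(u5, base_probs), orf, rand_bases(u3, base_probs))
    found <- find_longest_orf(seq)
    if (found$start == u5 && found$end == u5 + orf_len) {
      return(list(id = id, seq = seq, planted_start = u5,
                  planted_end = u5 + orf_len))
    }
  }
  abort("Could not place the planted ORF as the longest ORF after 1000 attempts.")
}

apply_indels <- function(seq, rate, base_probs) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  u <- stats::runif(length(chars))
  keep <- u >= rate / 2
  ins <- u >= rate / 2 & u < rate # insert a random base after this one
  out <- chars[keep]
  if (any(ins)) {
    pieces <- character(length(chars))
    pieces[keep] <- chars[keep]
    pieces[ins] <- paste0(chars[ins],
                          sample(c("A", "C", "G", "T"), sum(ins),
                                 replace = TRUE, prob = base_probs))
    out <- pieces[pieces != ""]
  }
  paste(out, collapse = "")
}

simulate_noncoding_one <- function(config, codon_probs, base_probs, id) {
  for (attempt in seq_len(10000L)) {
    if (config$indel_rate > 0) {
      template <- simulate_coding_one(config, codon_probs, base_probs, id)
      seq <- apply_indels(template$seq, config$indel_rate, base_probs)
    } else {
      len <- sample(config$len_range[1L]:config$len_range[2L], 1L)
      seq <- rand_bases(len, base_probs)
      if (stats::runif(1L) < config$sorf_prob) {
        sorf_cod <- sample(10:50, 1L) # 30-150 nt including start and stop
        sorf <- paste0("ATG",
                       paste(sample(SENSE_CODONS, sorf_cod - 2L,
                                    replace = TRUE), collapse = ""),
                       sample(STOP_CODONS, 1L))
        pos <- sample(0:(nchar(seq) - nchar(sorf)), 1L)
        seq <- paste0(substr(seq, 1L, pos), sorf,
                      substr(seq, pos + nchar(sorf) + 1L, nchar(seq)))
      }
    }
    found <- find_longest_orf(seq)
    if ((found$end - found$start) <= config$max_nc_orf) {
      return(list(id = id, seq = seq))
    }
  }
  abort("Rejection sampling failed after 10000 attempts; consider a larger `max_nc_orf`.")
}

#' Simulate a labeled synthetic transcript set
#'
#' Generates `n_coding` coding and `n_noncoding` noncoding transcripts under
#' a dataset-level codon-usage distribution drawn once from a symmetric
#' Dirichlet. Noncoding sequences match the mononucleotide composition of
#' the coding batch, so the classifier cannot separate the classes on base
#' content alone. The same config (including its seed) produces identical
#' output.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `id`, `seq`, `length`,
#'   `label` (`"coding"`/`"noncoding"`) and, for coding records, the planted
#'   ORF span `planted_start`/`planted_end` (0-based half-open; `NA` for
#'   noncoding).
#' @export
simulate_transcripts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    codon_probs <- draw_codon_probs(config$codon_bias_concentration)
    base_probs <- codon_base_probs(codon_probs)
    coding <- lapply(seq_len(config$n_coding), function(i) {
      simulate_coding_one(config, codon_probs, base_probs,
                          sprintf("cod_%05d", i))
    })
    noncoding <- lapply(seq_len(config$n_noncoding), function(i) {
      simulate_noncoding_one(config, codon_probs, base_probs,
                             sprintf("nc_%05d", i))
    })
    seqs <- c(vapply(coding, `[[`, character(1), "seq"),
              vapply(noncoding, `[[`, character(1), "seq"))
    tibble(
      id = c(vapply(coding, `[[`, character(1), "id"),
             vapply(noncoding, `[[`, character(1), "id")),
      seq = seqs,
      length = nchar(seqs),
      label = rep(c("coding", "noncoding"),
                  c(config$n_coding, config$n_noncoding)),
      planted_start = c(vapply(coding, function(x) as.integer(x$planted_start),
                               integer(1)),
                        rep(NA_integer_, config$n_noncoding)),
      planted_end = c(vapply(coding, function(x) as.integer(x$planted_end),
                             integer(1)),
                      rep(NA_integer_, config$n_noncoding))
    )
  })
}

#' Write a simulated dataset to FASTA files plus a labels TSV
#'
#' @param config A [synthetic_config()].
#' @param coding_path,noncoding_path,labels_path Output file paths. The
#'   labels TSV has columns `id` and `label`.
#' @return The simulated tibble (see [simulate_transcripts()]), invisibly.
#' @export
simulate_dataset <- function(config, coding_path, noncoding_path, labels_path) {
  dat <- simulate_transcripts(config)
  write_transcripts(dat[dat$label == "coding", ], coding_path)
  write_transcripts(dat[dat$label == "noncoding", ], noncoding_path)
  utils::write.table(dat[, c("id", "label")], labels_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dat)
}
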