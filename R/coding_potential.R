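# Deterministic coding-potential score: a weighted combination of
# ORF coverage, the Fickett TESTCODE statistic and an in-frame hexamer
# (dicodon) log-odds against a uniform background. Thresholded at 1 by the
# classification cascade, mirroring the decision point of SVM-based coding
# potential calculators without their live-database dependency.

# Fickett (1982) TESTCODE lookup tables, as commonly reproduced in coding
# potential tools.
.fickett <- list(
  position_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
  ),
  position_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  position_para = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0),
  content_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
  ),
  content_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14),
  content_para = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
)

.fickett_lookup <- function(value, para, prob) {
  idx <- which(value >= para)[1L]
  prob[[idx]]
}

#' Fickett TESTCODE statistic
#'
#' Position-asymmetry and base-content statistic discriminating coding from
#' non-coding nucleotide sequences; higher values indicate stronger
#' coding-like periodicity.
#'
#' @inheritParams find_orfs
#' @return a single numeric value.
#' @export
fickett_score <- function(sequence) {
  sequence <- check_sequence(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bases <- bases[bases != "N"]
  if (length(bases) < 3L) return(0)
  phase <- (seq_along(bases) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(bases == b & phase == p), numeric(1))
    pos_param <- max(cnt) / (min(cnt) + 1)
    content <- sum(cnt) / length(bases)
    score <- score +
      .fickett_lookup(pos_param, .fickett$position_para,
                      .fickett$position_prob[[b]]) *
        .fickett$position_weight[[b]] +
      .fickett_lookup(content, .fickett$content_para,
                      .fickett$content_prob[[b]]) *
        .fickett$content_weight[[b]]
  }
  score
}

#' Reference codon usage
#'
#' A generic metazoan-like codon usage prior: typical amino-acid composition
#' with geometrically decaying synonymous-codon preference. Used both by the
#' synthetic-data generator to emit coding ORFs and as the training prior of
#' the default hexamer model, playing the role that empirical coding-sequence
#' statistics play for database-trained coding potential tools.
#'
#' @return named numeric vector over the 64 codons, summing to 1.
#' @export
codon_usage_default <- function() {
  aa_freq <- c(
    A = 0.074, R = 0.042, N = 0.044, D = 0.059, C = 0.033, E = 0.058,
    Q = 0.037, G = 0.074, H = 0.029, I = 0.038, L = 0.076, K = 0.072,
    M = 0.018, F = 0.040, P = 0.050, S = 0.081, T = 0.062, W = 0.013,
    Y = 0.033, V = 0.068
  )
  code <- Biostrings::GENETIC_CODE
  usage <- setNames(numeric(length(code)), names(code))
  for (aa in names(aa_freq)) {
    syn <- sort(names(code)[code == aa])
    w <- 0.55^(seq_along(syn) - 1L)
    usage[syn] <- aa_freq[[aa]] * w / sum(w)
  }
  usage[names(code)[code == "*"]] <- 1e-4
  usage / sum(usage)
}

# log2 odds per hexamer: codon-pair probability under the coding usage
# against a uniform nucleotide background
.hexamer_env <- new.env(parent = emptyenv())

hexamer_model <- function(codon_usage = codon_usage_default()) {
  key <- paste(signif(codon_usage, 6), collapse = ",")
  cached <- .hexamer_env$model
  if (!is.null(cached) && identical(.hexamer_env$key, key)) return(cached)
  codons <- names(codon_usage)
  hex <- as.vector(outer(codons, codons, paste0))
  p_cod <- as.vector(outer(codon_usage, codon_usage))
  model <- setNames(log2(p_cod / (1 / 4096)), hex)
  .hexamer_env$model <- model
  .hexamer_env$key <- key
  model
}

#' In-frame hexamer log-odds of an ORF
#'
#' Mean log2 odds of the dicodons (step 3) of the longest ORF under the
#' coding hexamer model versus a uniform background; 0 when no ORF of at
#' least 4 codons exists. Hexamers containing `N` are skipped.
#'
#' @param sequence nucleotide string.
#' @param orfs ORF table from [find_orfs()]; computed if missing.
#' @param codon_usage codon usage prior for the model.
#' @return a single numeric value.
#' @export
hexamer_score <- function(sequence, orfs = NULL,
                          codon_usage = codon_usage_default()) {
  sequence <- check_sequence(sequence)
  if (is.null(orfs)) orfs <- find_orfs(sequence)
  if (nrow(orfs) == 0L || orfs$length_nt[[1L]] < 12L) return(0)
  top <- orfs[1L, ]
  strand_seq <- if (top$frame <= 3L) sequence else revcomp(sequence)
  orf_seq <- substr(strand_seq, top$start + 1L, top$end)
  orf_seq <- substr(orf_seq, 1L, nchar(orf_seq) - 3L)  # drop stop codon
  starts <- seq.int(1L, nchar(orf_seq) - 5L, by = 3L)
  hex <- substring(orf_seq, starts, starts + 5L)
  hex <- hex[!grepl("N", hex, fixed = TRUE)]
  if (length(hex) == 0L) return(0)
  model <- hexamer_model(codon_usage)
  mean(model[hex])
}

#' Coding-potential score of a transcript
#'
#' Weighted combination of three coding-evidence components, calibrated so
#' that transcripts carrying a substantial, codon-biased ORF score above 1
#' while long non-coding transcripts score at or below 1:
#' \deqn{score = w_{orf}\,cov + w_{fick}\,fickett + w_{hex}\,\max(hex, 0)}
#' where `cov` is longest-ORF length over transcript length.
#'
#' @inheritParams hexamer_score
#' @param weights named numeric vector with entries `orf`, `fickett`, `hex`.
#' @return one-row tibble with `orf_coverage`, `fickett`, `hexamer`,
#'   `cp_score`.
#' @export
coding_potential_score <- function(sequence, orfs = NULL,
                                   codon_usage = codon_usage_default(),
                                   weights = c(orf = 1.45, fickett = 0.55,
                                               hex = 0.10)) {
  sequence <- check_sequence(sequence)
  if (nchar(sequence) < 6L) abort("sequence shorter than 6 nt")
  if (is.null(orfs)) orfs <- find_orfs(sequence)
  cov <- if (nrow(orfs) == 0L) 0 else orfs$length_nt[[1L]] / nchar(sequence)
  fick <- fickett_score(sequence)
  hex <- hexamer_score(sequence, orfs, codon_usage)
  tibble(
    orf_coverage = cov, fickett = fick, hexamer = hex,
    cp_score = unname(weights[["orf"]] * cov + weights[["fickett"]] * fick +
                        weights[["hex"]] * max(hex, 0))
  )
}
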