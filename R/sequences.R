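#' Validate a nucleotide sequence
#'
#' Sequences are restricted to the unambiguous DNA alphabet plus `N`.
#' Lower-case input is accepted and upper-cased.
#'
#' @param sequence a single character string.
#' @return the validated, upper-cased sequence.
#' @keywords internal
check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    abort("`sequence` must be a single non-empty character string")
  }
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    abort(sprintf(
      "non-IUPAC character '%s' at position %d",
      substr(sequence, bad, bad), as.integer(bad)
    ))
  }
  sequence
}

revcomp <- function(sequence) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", sequence), "", fixed = TRUE)[[1]]),
        collapse = "")
}

stop_codons <- c("TAA", "TAG", "TGA")

# codons of a single frame (0-based frame offset 0..2), trailing partial
# codon dropped
frame_codons <- function(sequence, offset) {
  L <- nchar(sequence)
  starts <- seq.int(offset + 1L, by = 3L, length.out = (L - offset) %/% 3L)
  if (length(starts) == 0L) return(character(0))
  substring(sequence, starts, starts + 2L)
}

#' Find open reading frames on all six frames
#'
#' An ORF is an ATG-initiated codon run ending at the first in-frame stop
#' codon (stop included in the length). Every ATG yields its own call, so
#' nested starts sharing one stop are all reported. Frames are numbered 1-3
#' (forward) and 4-6 (reverse strand, i.e. frames of the reverse complement);
#' `start`/`end` are 0-based half-open offsets on the strand of the frame.
#'
#' @param sequence nucleotide string (A/C/G/T/N).
#' @param min_nt minimum ORF length in nt, stop codon included (default 6:
#'   ATG plus stop).
#' @param allow_no_stop if `TRUE`, an ATG run reaching the end of its frame
#'   without a stop is also reported (length without stop). Default `FALSE`.
#' @return a tibble with columns `frame`, `start`, `end`, `length_nt`,
#'   sorted by decreasing `length_nt`, ties by (`frame`, `start`).
#' @export
#' @examples
#' find_orfs("ATGAAATAA")
find_orfs <- function(sequence, min_nt = 6L, allow_no_stop = FALSE) {
  sequence <- check_sequence(sequence)
  strands <- c(sequence, revcomp(sequence))
  out <- vector("list", 6L)
  for (f in 1:6) {
    s <- strands[[(f - 1L) %/% 3L + 1L]]
    offset <- (f - 1L) %% 3L
    codons <- frame_codons(s, offset)
    atg <- which(codons == "ATG")
    if (length(atg) == 0L) next
    stops <- which(codons %in% stop_codons)
    # first stop at or after each ATG
    idx <- findInterval(atg - 1L, stops) + 1L
    has_stop <- idx <= length(stops)
    stop_at <- rep(NA_integer_, length(atg))
    stop_at[has_stop] <- stops[idx[has_stop]]
    len <- ifelse(has_stop, (stop_at - atg + 1L) * 3L,
                  if (allow_no_stop) (length(codons) - atg + 1L) * 3L
                  else NA_integer_)
    keep <- !is.na(len) & len >= min_nt
    if (!any(keep)) next
    start0 <- offset + (atg[keep] - 1L) * 3L
    out[[f]] <- tibble(
      frame = f, start = start0, end = start0 + len[keep],
      length_nt = as.integer(len[keep])
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(frame = integer(), start = integer(), end = integer(),
                  length_nt = integer()))
  }
  arrange(res, dplyr::desc(.data$length_nt), .data$frame, .data$start)
}

#' Longest ORF length of a sequence
#'
#' @inheritParams find_orfs
#' @return integer nt length (0 if no ORF).
#' @export
longest_orf <- function(sequence, allow_no_stop = FALSE) {
  orfs <- find_orfs(sequence, allow_no_stop = allow_no_stop)
  if (nrow(orfs) == 0L) 0L else orfs$length_nt[[1L]]
}

#' Translate a nucleotide sequence in all six frames
#'
#' Standard genetic code; stop codons are rendered as `*`, codons containing
#' `N` as `X`; trailing partial codons are dropped. Frames are ordered
#' +1, +2, +3, -1, -2, -3, where frame -k is frame +k of the reverse
#' complement.
#'
#' @inheritParams find_orfs
#' @return named character vector of 6 peptides (`F1`..`F3`, `R1`..`R3`).
#' @export
#' @examples
#' translate_six_frames("ATGTTTTAA")[["F1"]]
translate_six_frames <- function(sequence) {
  sequence <- check_sequence(sequence)
  strands <- c(sequence, revcomp(sequence))
  peptides <- character(6)
  for (f in 1:6) {
    s <- strands[[(f - 1L) %/% 3L + 1L]]
    offset <- (f - 1L) %% 3L
    L <- nchar(s)
    nc <- (L - offset) %/% 3L
    if (nc == 0L) {
      peptides[f] <- ""
      next
    }
    sub <- Biostrings::DNAString(substr(s, offset + 1L, offset + 3L * nc))
    peptides[f] <- as.character(
      Biostrings::translate(sub, no.init.codon = TRUE, if.fuzzy.codon = "X")
    )
  }
  setNames(peptides, c("F1", "F2", "F3", "R1", "R2", "R3"))
}
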