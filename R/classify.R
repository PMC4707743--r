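#' Read transcripts from FASTA into a tibble
#'
#' FASTA headers of the form `id gene=GENE` populate `gene_id`; otherwise
#' `gene_id` defaults to the transcript id.
#'
#' @param path FASTA file.
#' @return tibble with `id`, `gene_id`, `sequence`, `length`.
#' @export
read_transcripts <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  id <- sub("\\s.*$", "", headers)
  gene <- ifelse(grepl("gene=", headers),
                 sub(".*gene=(\\S+).*", "\\1", headers), id)
  tibble(id = id, gene_id = gene,
         sequence = as.character(seqs), length = Biostrings::width(seqs))
}

#' Write transcripts to FASTA
#'
#' @param transcripts tibble with `id`, `gene_id`, `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(transcripts$sequence)
  names(seqs) <- paste0(transcripts$id, " gene=", transcripts$gene_id)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

hit_sources <- c("blastx_refseq", "pfam_hmm", "blastp_refseq")

#' Read a homology hit table
#'
#' Tab-separated, BLAST outfmt-6-like: columns `query`, `subject`, `pident`,
#' `length`, `evalue`, `bitscore`; lines starting with `#` are comments.
#'
#' @param path TSV file.
#' @param source evidence source label, one of `blastx_refseq`, `pfam_hmm`,
#'   `blastp_refseq`.
#' @return tibble with a `source` column appended.
#' @export
read_hits <- function(path, source) {
  source <- match.arg(source, hit_sources)
  df <- readr::read_tsv(
    path, comment = "#",
    col_names = c("query_id", "subject_id", "pident", "length", "evalue",
                  "bitscore"),
    col_types = "ccdidd", progress = FALSE
  )
  mutate(df, source = source)
}

#' Write a homology hit table
#'
#' @param hits tibble as returned by [read_hits()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  writeLines("# query\tsubject\tpident\tlength\tevalue\tbitscore", path)
  readr::write_tsv(
    select(hits, "query_id", "subject_id", "pident", "length", "evalue",
           "bitscore"),
    path, col_names = FALSE, append = TRUE, progress = FALSE
  )
  invisible(path)
}

#' Classify transcripts into coding / lncRNA candidates / discarded
#'
#' Tiered evidence cascade; the first firing rule decides and is recorded:
#' \enumerate{
#'   \item longest ORF >= `min_orf` nt: `coding`;
#'   \item length < `min_nc_len` nt: discarded (`too_short`);
#'   \item any `blastx_refseq` hit with e-value < `evalue_blastx`:
#'     discarded (`blastx_hit`);
#'   \item any `pfam_hmm` hit with e-value < `evalue_pfam`:
#'     discarded (`pfam_hit`);
#'   \item any `blastp_refseq` hit with e-value < `evalue_blastp`:
#'     discarded (`blastp_hit`);
#'   \item coding-potential score > `cp_threshold`:
#'     discarded (`coding_potential`);
#'   \item otherwise `lncRNA_candidate`.
#' }
#' Defaults are deliberately conservative screening thresholds: ORF
#' 300 nt, minimum non-coding length 600 nt, e-value gates 10 / 0.01 / 10,
#' coding-potential threshold 1.
#'
#' @param transcripts tibble from [read_transcripts()].
#' @param hits homology hit tibble (any mix of sources), or `NULL`.
#' @param cp_threshold coding-potential discard threshold.
#' @param min_orf minimum ORF length (nt, stop included) calling coding.
#' @param min_nc_len minimum transcript length (nt) for a non-coding
#'   candidate.
#' @param evalue_blastx,evalue_pfam,evalue_blastp e-value gates per source.
#' @param cp_scores optional tibble (`id`, `cp_score`) overriding the
#'   built-in coding-potential score (e.g. from an external calculator).
#' @param allow_no_stop passed to [find_orfs()].
#' @return tibble with `id`, `gene_id`, `length`, `label`, `discard_reason`,
#'   `longest_orf_nt`, `cp_score` (NA where the cascade stopped earlier).
#' @export
classify_transcripts <- function(transcripts, hits = NULL, cp_threshold = 1,
                                 min_orf = 300L, min_nc_len = 600L,
                                 evalue_blastx = 10, evalue_pfam = 0.01,
                                 evalue_blastp = 10, cp_scores = NULL,
                                 allow_no_stop = FALSE) {
  stopifnot(min_orf > 0, min_nc_len > 0)
  if (is.null(hits)) {
    hits <- tibble(query_id = character(), source = character(),
                   evalue = numeric())
  }
  unknown <- setdiff(unique(hits$query_id), transcripts$id)
  if (length(unknown) > 0L) {
    warn(sprintf("%d hit(s) reference unknown transcript ids; ignored",
                 sum(hits$query_id %in% unknown)))
    hits <- filter(hits, !.data$query_id %in% unknown)
  }
  gates <- c(blastx_refseq = evalue_blastx, pfam_hmm = evalue_pfam,
             blastp_refseq = evalue_blastp)
  hit_flags <- function(src) {
    h <- filter(hits, .data$source == src, .data$evalue < gates[[src]])
    transcripts$id %in% unique(h$query_id)
  }
  has_blastx <- hit_flags("blastx_refseq")
  has_pfam <- hit_flags("pfam_hmm")
  has_blastp <- hit_flags("blastp_refseq")

  n <- nrow(transcripts)
  orf_nt <- integer(n)
  orf_tabs <- vector("list", n)
  for (i in seq_len(n)) {
    orf_tabs[[i]] <- find_orfs(transcripts$sequence[[i]],
                               allow_no_stop = allow_no_stop)
    orf_nt[i] <- if (nrow(orf_tabs[[i]]) == 0L) 0L
                 else orf_tabs[[i]]$length_nt[[1L]]
  }

  label <- character(n)
  reason <- character(n)
  cp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (orf_nt[i] >= min_orf) {
      label[i] <- "coding"; reason[i] <- ""
    } else if (transcripts$length[[i]] < min_nc_len) {
      label[i] <- "discarded"; reason[i] <- "too_short"
    } else if (has_blastx[i]) {
      label[i] <- "discarded"; reason[i] <- "blastx_hit"
    } else if (has_pfam[i]) {
      label[i] <- "discarded"; reason[i] <- "pfam_hit"
    } else if (has_blastp[i]) {
      label[i] <- "discarded"; reason[i] <- "blastp_hit"
    } else {
      cp[i] <- if (!is.null(cp_scores)) {
        sc <- cp_scores$cp_score[match(transcripts$id[[i]], cp_scores$id)]
        if (is.na(sc)) abort(sprintf("no external cp score for '%s'",
                                     transcripts$id[[i]]))
        sc
      } else {
        coding_potential_score(transcripts$sequence[[i]],
                               orfs = orf_tabs[[i]])$cp_score
      }
      if (cp[i] > cp_threshold) {
        label[i] <- "discarded"; reason[i] <- "coding_potential"
      } else {
        label[i] <- "lncRNA_candidate"; reason[i] <- ""
      }
    }
  }
  tibble(
    id = transcripts$id, gene_id = transcripts$gene_id,
    length = transcripts$length, label = label, discard_reason = reason,
    longest_orf_nt = orf_nt, cp_score = cp
  )
}
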