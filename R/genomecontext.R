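# Gene models are tibbles with one row per gene:
#   gene_id, scaffold, strand ('+'/'-'), kind ('coding'/'noncoding'),
#   cds_start, cds_end (NA for noncoding), exons (list-column of tibbles
#   with start/end).
# Internal coordinates are 0-based half-open; GFF3 I/O converts to and from
# 1-based inclusive.

#' Construct a gene-model tibble
#'
#' @param gene_id,scaffold,strand,kind per-gene character vectors.
#' @param exons list of tibbles/data frames with 0-based half-open
#'   `start`/`end` columns, one per gene.
#' @param cds_start,cds_end 0-based half-open CDS genomic span (NA for
#'   noncoding genes).
#' @return validated gene-model tibble sorted by scaffold and start.
#' @export
gene_models <- function(gene_id, scaffold, strand, kind, exons,
                        cds_start = NA_integer_, cds_end = NA_integer_) {
  exons <- purrr::map(exons, function(e) {
    e <- arrange(as_tibble(e)[, c("start", "end")], .data$start)
    if (any(e$end <= e$start)) abort("exon with non-positive width")
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      abort("overlapping exons within one gene")
    }
    e
  })
  out <- tibble(
    gene_id = as.character(gene_id), scaffold = as.character(scaffold),
    strand = as.character(strand), kind = as.character(kind),
    cds_start = as.integer(rep_len(cds_start, length(gene_id))),
    cds_end = as.integer(rep_len(cds_end, length(gene_id))),
    exons = exons
  )
  out$start <- purrr::map_int(out$exons, ~ min(.x$start))
  out$end <- purrr::map_int(out$exons, ~ max(.x$end))
  stopifnot(all(out$strand %in% c("+", "-")),
            all(out$kind %in% c("coding", "noncoding")))
  arrange(out, .data$scaffold, .data$start, .data$gene_id)
}

#' Derive introns of gene models
#'
#' Introns are the gaps between consecutive exons; single-exon genes have
#' none.
#'
#' @param models gene-model tibble.
#' @return tibble `gene_id`, `scaffold`, `start`, `end` (0-based half-open).
#' @export
gene_introns <- function(models) {
  rows <- purrr::pmap(
    list(models$gene_id, models$scaffold, models$exons),
    function(gid, sc, ex) {
      if (nrow(ex) < 2L) return(NULL)
      tibble(gene_id = gid, scaffold = sc,
             start = ex$end[-nrow(ex)], end = ex$start[-1L])
    }
  )
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(gene_id = character(), scaffold = character(),
                  start = integer(), end = integer()))
  }
  out
}

#' Write gene models to GFF3
#'
#' Emits gene / mRNA / exon features, plus CDS features (exon pieces
#' intersecting the CDS span) for coding genes. 1-based inclusive on disk.
#'
#' @param models gene-model tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  recs <- purrr::pmap(
    list(models$gene_id, models$scaffold, models$strand, models$kind,
         models$cds_start, models$cds_end, models$exons,
         models$start, models$end),
    function(gid, sc, strand, kind, cs, ce, ex, gs, ge) {
      tid <- paste0(gid, ".t1")
      rows <- list(
        tibble(seqid = sc, type = c("gene", "mRNA"),
               start = gs + 1L, end = ge, strand = strand,
               ID = c(gid, tid), Parent = c(NA, gid),
               kind = c(kind, NA)),
        tibble(seqid = sc, type = "exon", start = ex$start + 1L,
               end = ex$end, strand = strand,
               ID = paste0(tid, ".exon", seq_len(nrow(ex))), Parent = tid,
               kind = NA)
      )
      if (kind == "coding" && !is.na(cs)) {
        cds <- filter(ex, .data$end > cs, .data$start < ce)
        cds <- mutate(cds, start = pmax(.data$start, cs),
                      end = pmin(.data$end, ce))
        widths <- cds$end - cds$start
        # phase in translation order (genomic order for '+', reversed for '-')
        cum <- if (strand == "+") cumsum(c(0L, head(widths, -1L)))
               else rev(cumsum(c(0L, head(rev(widths), -1L))))
        rows <- c(rows, list(
          tibble(seqid = sc, type = "CDS",
                 start = cds$start + 1L, end = cds$end, strand = strand,
                 ID = paste0(tid, ".cds", seq_len(nrow(cds))), Parent = tid,
                 kind = NA, phase = (3L - cum %% 3L) %% 3L)
        ))
      }
      bind_rows(rows)
    }
  )
  df <- bind_rows(recs)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$kind <- df$kind
  if (!"phase" %in% names(df)) df$phase <- NA_integer_
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Inverse of [write_gene_models_gff3()]; also accepts generic GFF3 with
#' gene/exon/CDS features (genes lacking a `kind` attribute are `coding`
#' when they carry CDS features, else `noncoding`).
#'
#' @param path GFF3 file.
#' @param genome optional named vector of scaffold lengths; coordinates are
#'   validated against it.
#' @return gene-model tibble.
#' @export
read_gene_models_gff3 <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]]), character(1))
  genes <- filter(df, .data$type == "gene")
  mrna <- filter(df, .data$type == "mRNA")
  tx2gene <- setNames(mrna$Parent, mrna$ID)
  feat <- filter(df, .data$type %in% c("exon", "CDS"))
  feat$gene_id <- dplyr::coalesce(tx2gene[feat$Parent],
                                  as.character(feat$Parent))
  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[[i]]
    ex <- filter(feat, .data$gene_id == gid, .data$type == "exon")
    if (nrow(ex) == 0L) {
      ex <- genes[i, ]  # exonless record: gene span is one exon
    }
    cds <- filter(feat, .data$gene_id == gid, .data$type == "CDS")
    kind <- if ("kind" %in% names(genes)) genes$kind[[i]] else NA_character_
    if (is.na(kind)) kind <- if (nrow(cds) > 0L) "coding" else "noncoding"
    list(
      gene_id = gid, scaffold = as.character(genes$seqnames[[i]]),
      strand = as.character(genes$strand[[i]]), kind = kind,
      exons = tibble(start = ex$start - 1L, end = ex$end),
      cds_start = if (nrow(cds) > 0L) min(cds$start) - 1L else NA_integer_,
      cds_end = if (nrow(cds) > 0L) max(cds$end) else NA_integer_
    )
  })
  models <- gene_models(
    gene_id = purrr::map_chr(out, "gene_id"),
    scaffold = purrr::map_chr(out, "scaffold"),
    strand = purrr::map_chr(out, "strand"),
    kind = purrr::map_chr(out, "kind"),
    exons = purrr::map(out, "exons"),
    cds_start = purrr::map_int(out, "cds_start"),
    cds_end = purrr::map_int(out, "cds_end")
  )
  if (!is.null(genome)) {
    bad <- models$gene_id[
      models$end > unname(genome[models$scaffold]) | models$start < 0L |
        is.na(genome[models$scaffold])
    ]
    if (length(bad) > 0L) {
      abort(sprintf("feature(s) out of genome bounds: %s",
                    paste(head(bad, 5L), collapse = ", ")))
    }
  }
  models
}

# flatten a set of (scaffold, start, end) rows into a GRanges
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# exon pieces of each gene, as rows (gene_id, scaffold, start, end)
.exon_rows <- function(models) {
  tidyr::unnest(select(models, "gene_id", "scaffold", "exons"),
                "exons")
}

#' Remove lncRNA candidates overlapping coding ORFs or introns
#'
#' A candidate is removed when any of its exons intersects (>= 1 bp, either
#' strand) the CDS-covered exonic region or an intron of any coding gene.
#' Overlap with coding UTR exons alone does not remove a candidate but is
#' flagged, unless `strict_exon_overlap = TRUE`, in which case any coding
#' exon overlap removes. Survivors are the long intergenic non-coding RNAs
#' (lincRNAs).
#'
#' @param candidates gene-model tibble of lncRNA candidate loci.
#' @param coding gene-model tibble of coding genes (rows with
#'   `kind != "coding"` are ignored).
#' @param strict_exon_overlap treat all coding exons as removing.
#' @return list with `lincRNA` and `removed` gene-model tibbles and
#'   `decisions`, a tibble (`gene_id`, `removed`, `overlap_cds`,
#'   `overlap_intron`, `overlap_utr`).
#' @export
intergenic_filter <- function(candidates, coding,
                              strict_exon_overlap = FALSE) {
  coding <- filter(coding, .data$kind == "coding")
  dec <- tibble(gene_id = candidates$gene_id, overlap_cds = FALSE,
                overlap_intron = FALSE, overlap_utr = FALSE)
  if (nrow(coding) > 0L && nrow(candidates) > 0L) {
    cand_ex <- .exon_rows(candidates)
    cand_gr <- .as_granges(cand_ex)
    cod_ex <- .exon_rows(coding)
    cod_ex <- left_join(cod_ex,
                        select(coding, "gene_id", "cds_start", "cds_end"),
                        by = "gene_id")
    cds_part <- filter(cod_ex, !is.na(.data$cds_start),
                       .data$end > .data$cds_start,
                       .data$start < .data$cds_end)
    cds_part <- mutate(cds_part, start = pmax(.data$start, .data$cds_start),
                       end = pmin(.data$end, .data$cds_end))
    hit_any <- function(target) {
      if (nrow(target) == 0L) return(character(0))
      ov <- GenomicRanges::findOverlaps(cand_gr, .as_granges(target),
                                        ignore.strand = TRUE)
      unique(cand_ex$gene_id[S4Vectors::queryHits(ov)])
    }
    utr_part <- bind_rows(
      filter(cod_ex, is.na(.data$cds_start) | .data$end <= .data$cds_start |
               .data$start >= .data$cds_end),
      mutate(filter(cod_ex, !is.na(.data$cds_start),
                    .data$start < .data$cds_start,
                    .data$end > .data$cds_start),
             end = .data$cds_start),
      mutate(filter(cod_ex, !is.na(.data$cds_start),
                    .data$end > .data$cds_end,
                    .data$start < .data$cds_end),
             start = .data$cds_end)
    )
    utr_part <- filter(utr_part, .data$end > .data$start)
    dec$overlap_cds <- dec$gene_id %in% hit_any(cds_part)
    dec$overlap_intron <- dec$gene_id %in% hit_any(gene_introns(coding))
    dec$overlap_utr <- dec$gene_id %in% hit_any(utr_part)
  }
  dec$removed <- dec$overlap_cds | dec$overlap_intron |
    (strict_exon_overlap & dec$overlap_utr)
  list(
    lincRNA = candidates[!dec$removed, , drop = FALSE],
    removed = candidates[dec$removed, , drop = FALSE],
    decisions = select(dec, "gene_id", "removed", "overlap_cds",
                       "overlap_intron", "overlap_utr")
  )
}

#' Nearest coding neighbours of lincRNA loci
#'
#' For each lincRNA gene, the closest coding gene on the same scaffold on
#' each side of the genome forward axis (upstream = left, downstream =
#' right). Distance is the gap between the closest span ends (0 if abutting
#' or overlapping); ties are broken by lexicographically smaller `gene_id`.
#' A side with no coding gene is omitted.
#'
#' @param linc gene-model tibble of lincRNA loci.
#' @param coding gene-model tibble of coding genes.
#' @return tibble `linc_gene_id`, `neighbor_gene_id`, `side`, `distance`.
#' @export
nearest_coding_neighbors <- function(linc, coding) {
  coding <- filter(coding, .data$kind == "coding")
  empty <- tibble(linc_gene_id = character(), neighbor_gene_id = character(),
                  side = character(), distance = integer())
  if (nrow(linc) == 0L || nrow(coding) == 0L) return(empty)
  res <- purrr::map(split(linc, linc$scaffold), function(lc) {
    cod <- filter(coding, .data$scaffold == lc$scaffold[[1L]])
    if (nrow(cod) == 0L) return(NULL)
    purrr::pmap(list(lc$gene_id, lc$start, lc$end), function(gid, s, e) {
      gap_left <- s - cod$end     # >= 0 when gene entirely left
      gap_right <- cod$start - e  # >= 0 when gene entirely right
      overlaps <- gap_left < 0L & gap_right < 0L
      side <- ifelse(overlaps,
                     ifelse(cod$start <= s, "upstream", "downstream"),
                     ifelse(gap_left >= 0L, "upstream", "downstream"))
      dist <- ifelse(overlaps, 0L, pmax(gap_left, gap_right))
      cand <- tibble(neighbor_gene_id = cod$gene_id, side = side,
                     distance = as.integer(dist))
      best <- dplyr::slice_head(
        arrange(group_by(cand, .data$side), .data$distance,
                .data$neighbor_gene_id),
        n = 1L
      )
      mutate(ungroup(best), linc_gene_id = gid)
    })
  })
  out <- bind_rows(purrr::flatten(res[!vapply(res, is.null, logical(1))]))
  if (nrow(out) == 0L) return(empty)
  select(arrange(out, .data$linc_gene_id, .data$side),
         "linc_gene_id", "neighbor_gene_id", "side", "distance")
}
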