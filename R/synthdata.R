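# Synthetic study generator: a toy multi-scaffold genome carrying coding
# genes and intergenic non-coding loci, decoy transcripts, homology-hit
# tables and stage-structured negative-binomial count matrices, all with
# planted truth, so that every downstream stage of the pipeline can be
# exercised and scored without external data.

#' Simulation configuration
#'
#' Defaults define the reference synthetic study: 5 scaffolds of 250 kb;
#' 200 coding genes, 200 lincRNA loci, 50 pseudogene-like decoys (planted
#' homology hits), 50 decoys overlapping coding genes, 50 short decoys; a
#' non-reproductive baseline plus 8 developmental stages with 3 replicates;
#' NB dispersion 0.1; planted 4-fold upregulation; 4 planted co-expression
#' modules of 40 genes with within-module correlation 0.8; 20 planted
#' correlated lincRNA-neighbour pairs.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @param n_scaffolds,scaffold_len genome shape.
#' @param n_coding,n_linc,n_pseudo_decoys,n_overlap_decoys,n_short_decoys
#'   locus counts per class.
#' @param stages ordered condition names; the first is the non-reproductive
#'   baseline.
#' @param reps_per_stage libraries per condition.
#' @param nb_dispersion NB dispersion (0 gives Poisson counts).
#' @param planted_fold_change fold change of planted upregulation (1 plants
#'   none).
#' @param n_modules,module_size planted co-expression modules.
#' @param module_cor planted within-module expression correlation.
#' @param n_correlated_pairs planted lincRNA-neighbour correlated pairs.
#' @param de_fraction fraction of coding and lincRNA genes planted as
#'   stage-upregulated.
#' @param depth_sd standard deviation of log library depth (0 for equal
#'   depths).
#' @param gc genome GC content.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_scaffolds = 5L, scaffold_len = 250000L,
                       n_coding = 200L, n_linc = 200L,
                       n_pseudo_decoys = 50L, n_overlap_decoys = 50L,
                       n_short_decoys = 50L,
                       stages = c("nonreproductive", "vitellogenesis",
                                  "fertilization", "early_cleavage",
                                  "late_cleavage", "early_preinversion",
                                  "late_preinversion", "postinversion",
                                  "larva"),
                       reps_per_stage = 3L, nb_dispersion = 0.1,
                       planted_fold_change = 4, n_modules = 4L,
                       module_size = 40L, module_cor = 0.8,
                       n_correlated_pairs = 20L, de_fraction = 0.3,
                       depth_sd = 0.25, gc = 0.45) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_len = as.integer(scaffold_len),
              n_coding = as.integer(n_coding), n_linc = as.integer(n_linc),
              n_pseudo_decoys = as.integer(n_pseudo_decoys),
              n_overlap_decoys = as.integer(n_overlap_decoys),
              n_short_decoys = as.integer(n_short_decoys),
              stages = as.character(stages),
              reps_per_stage = as.integer(reps_per_stage),
              nb_dispersion = nb_dispersion,
              planted_fold_change = planted_fold_change,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_cor = module_cor,
              n_correlated_pairs = as.integer(n_correlated_pairs),
              de_fraction = de_fraction, depth_sd = depth_sd, gc = gc)
  with(cfg, {
    stopifnot(length(stages) >= 2L, !anyDuplicated(stages),
              reps_per_stage >= 2L, nb_dispersion >= 0,
              planted_fold_change > 0, module_cor >= 0, module_cor <= 1,
              de_fraction >= 0, de_fraction <= 1, depth_sd >= 0,
              gc > 0, gc < 1,
              n_scaffolds >= 1L, scaffold_len > 0L)
    stopifnot(all(c(n_coding, n_linc, n_pseudo_decoys, n_overlap_decoys,
                    n_short_decoys) >= 0L))
    if (n_overlap_decoys > 0L && n_coding < n_overlap_decoys) {
      abort("need at least one coding gene per overlap decoy")
    }
    if (n_modules > 0L && module_size < 30L) {
      abort("module_size must be >= 30, the minimum module size used downstream")
    }
    if (n_modules > length(stages)) {
      abort("n_modules cannot exceed the number of stages (module profiles are orthogonal stage programs)")
    }
  })
  structure(cfg, class = "sim_config")
}

.random_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random sequence with longest ORF below max_orf (rejection sampling)
.noncoding_seq <- function(n, gc, max_orf = 300L) {
  for (i in 1:200) {
    s <- .random_seq(n, gc)
    if (longest_orf(s) < max_orf) return(s)
  }
  abort("could not sample a non-coding sequence; constraints too tight")
}

.coding_transcript <- function(usage) {
  utr5 <- sample(50:150, 1L)
  n_codon <- sample(100:300, 1L)
  utr3 <- sample(50:200, 1L)
  sense <- usage[!names(usage) %in% stop_codons]
  body <- sample(names(sense), n_codon - 2L, replace = TRUE,
                 prob = sense / sum(sense))
  orf <- paste0("ATG", paste(body, collapse = ""),
                sample(stop_codons, 1L))
  list(
    sequence = paste0(.random_seq(utr5, 0.45), orf, .random_seq(utr3, 0.45)),
    orf_start = utr5, orf_end = utr5 + 3L * n_codon
  )
}

# map a transcript interval [t1, t2) onto genome intervals, given exon
# lengths in transcript order, intron lengths, strand and genome start
.map_tx_interval <- function(el, il, strand, g0, t1, t2) {
  k <- length(el)
  tx_start <- cumsum(c(0L, el))[seq_len(k)]
  gel <- if (strand == "+") el else rev(el)
  gil <- if (strand == "+") il else rev(il)
  gstart <- g0 + cumsum(c(0L, head(gel, -1L) + gil))
  pieces <- purrr::map(seq_len(k), function(j) {
    lo <- max(t1, tx_start[j])
    hi <- min(t2, tx_start[j] + el[j])
    if (hi <= lo) return(NULL)
    if (strand == "+") {
      off <- lo - tx_start[j]
      c(gstart[j] + off, gstart[j] + off + (hi - lo))
    } else {
      gj <- k - j + 1L  # genome exon index for transcript piece j
      off <- (tx_start[j] + el[j]) - hi
      c(gstart[gj] + off, gstart[gj] + off + (hi - lo))
    }
  })
  pieces <- purrr::compact(pieces)
  m <- do.call(rbind, pieces)
  tibble(start = as.integer(m[, 1L]), end = as.integer(m[, 2L]))
}

#' Simulate a toy genome with planted transcript classes
#'
#' Generates scaffold sequences, gene models, transcript sequences,
#' homology-hit tables and the planted truth. Coding transcripts carry a
#' codon-biased ORF of at least 300 nt; planted lincRNAs are >= 600 nt with
#' no ORF >= 300 nt, receive no hits, and their loci are intergenic;
#' pseudogene decoys carry planted hits below the cascade's e-value gates;
#' overlap decoys sit inside introns of coding genes; short decoys are
#' < 600 nt.
#'
#' @param config a [sim_config()].
#' @return object of class `linc_sim`: list with `genome` (named character
#'   vector), `models` (gene-model tibble), `transcripts`, `hits`, `truth`
#'   (list of tibbles: `classes`, `de`, `modules`, `pairs`) and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  usage <- codon_usage_default()

  specs <- list()
  add <- function(class, n, maker) {
    if (n == 0L) return()
    for (i in seq_len(n)) {
      specs[[length(specs) + 1L]] <<- c(maker(i), list(class = class))
    }
  }
  add("coding", config$n_coding, function(i) {
    tx <- .coding_transcript(usage)
    c(tx, list(length = nchar(tx$sequence)))
  })
  add("lincRNA", config$n_linc, function(i) {
    n <- sample(600:1500, 1L)
    list(sequence = .noncoding_seq(n, config$gc), length = n,
         orf_start = NA_integer_, orf_end = NA_integer_)
  })
  add("pseudogene_decoy", config$n_pseudo_decoys, function(i) {
    n <- sample(600:1500, 1L)
    list(sequence = .noncoding_seq(n, config$gc), length = n,
         orf_start = NA_integer_, orf_end = NA_integer_)
  })
  add("short_decoy", config$n_short_decoys, function(i) {
    n <- sample(200:599, 1L)
    list(sequence = .noncoding_seq(n, config$gc), length = n,
         orf_start = NA_integer_, orf_end = NA_integer_)
  })
  add("overlap_decoy", config$n_overlap_decoys, function(i) {
    n <- sample(600:1200, 1L)
    list(sequence = .noncoding_seq(n, config$gc), length = n,
         orf_start = NA_integer_, orf_end = NA_integer_)
  })
  classes <- purrr::map_chr(specs, "class")
  prefix <- c(coding = "cg", lincRNA = "lnc", pseudogene_decoy = "psd",
              short_decoy = "shd", overlap_decoy = "ovd")
  gene_ids <- paste0(prefix[classes],
                     stats::ave(seq_along(classes), classes,
                                FUN = seq_along))
  ov_idx <- which(classes == "overlap_decoy")
  host_idx <- head(which(classes == "coding"), length(ov_idx))

  # exon/intron structure; overlap-decoy hosts get a widened intron
  n_loci <- length(specs)
  struct <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    L <- specs[[i]]$length
    if (classes[i] == "coding") {
      k <- sample(1:4, 1L)
      host_pos <- match(i, host_idx)
      if (!is.na(host_pos)) k <- max(k, 2L)
      el <- if (k == 1L) L else {
        cuts <- sort(sample(seq(60L, L - 60L, by = 30L), k - 1L))
        diff(c(0L, cuts, L))
      }
      il <- if (k == 1L) integer(0) else sample(200:400, k - 1L,
                                                replace = TRUE)
      if (!is.na(host_pos)) {
        slot <- sample(seq_len(k - 1L), 1L)
        il[slot] <- specs[[ov_idx[host_pos]]]$length + sample(150:300, 1L)
        struct[[i]] <- list(el = el, il = il, host_intron = slot,
                            decoy = ov_idx[host_pos])
        next
      }
    } else if (classes[i] %in% c("lincRNA", "pseudogene_decoy")) {
      k <- sample(1:2, 1L, prob = c(0.7, 0.3))
      el <- if (k == 1L) L else {
        cut <- sample(seq(100L, L - 100L, by = 10L), 1L)
        c(cut, L - cut)
      }
      il <- if (k == 1L) integer(0) else sample(200:400, 1L)
      struct[[i]] <- list(el = el, il = il)
      next
    } else {
      struct[[i]] <- list(el = specs[[i]]$length, il = integer(0))
      next
    }
    struct[[i]] <- list(el = el, il = il)
  }

  # greedy packing of non-decoy loci onto scaffolds
  placeable <- setdiff(seq_len(n_loci), ov_idx)
  order_place <- sample(placeable)
  cursor <- rep(1L, config$n_scaffolds)  # 1-based next free position
  placement <- vector("list", n_loci)
  for (i in order_place) {
    fp <- sum(struct[[i]]$el) + sum(struct[[i]]$il)
    gap <- sample(300:800, 1L)
    sc <- which(cursor + gap + fp <= config$scaffold_len + 1L)
    if (length(sc) == 0L) {
      abort(sprintf(
        paste0("infeasible packing: locus of %d nt does not fit any ",
               "scaffold (n_scaffolds = %d, scaffold_len = %d)"),
        fp, config$n_scaffolds, config$scaffold_len
      ))
    }
    sc <- sc[[1L]]
    g0 <- cursor[sc] + gap - 1L  # 0-based start
    cursor[sc] <- cursor[sc] + gap + fp
    placement[[i]] <- list(scaffold = sc, g0 = g0,
                           strand = sample(c("+", "-"), 1L))
  }
  # overlap decoys inside their host's widened intron
  for (j in seq_along(ov_idx)) {
    i <- ov_idx[j]
    host <- host_idx[j]
    st <- struct[[host]]
    pl <- placement[[host]]
    gel <- if (pl$strand == "+") st$el else rev(st$el)
    gil <- if (pl$strand == "+") st$il else rev(st$il)
    gslot <- if (pl$strand == "+") st$host_intron
             else length(st$il) - st$host_intron + 1L
    intron_start <- pl$g0 + sum(gel[seq_len(gslot)]) +
      sum(gil[seq_len(gslot - 1L)])
    intron_len <- gil[gslot]
    slack <- intron_len - specs[[i]]$length
    off <- sample(seq(50L, slack - 50L), 1L)
    placement[[i]] <- list(scaffold = pl$scaffold,
                           g0 = intron_start + off,
                           strand = sample(c("+", "-"), 1L))
  }

  # scaffold backgrounds, then write exon sequences in
  scaffold_names <- sprintf("scaffold_%02d", seq_len(config$n_scaffolds))
  genome <- vapply(seq_len(config$n_scaffolds), function(s)
    .random_seq(config$scaffold_len, config$gc), character(1))
  names(genome) <- scaffold_names
  exon_tabs <- vector("list", n_loci)
  write_order <- c(setdiff(seq_len(n_loci), ov_idx), ov_idx)
  for (i in write_order) {
    st <- struct[[i]]
    pl <- placement[[i]]
    ex <- .map_tx_interval(st$el, st$il, pl$strand, pl$g0, 0L,
                           specs[[i]]$length)
    ex <- arrange(ex, .data$start)
    exon_tabs[[i]] <- ex
    k <- length(st$el)
    tx_start <- cumsum(c(0L, st$el))[seq_len(k)]
    for (j in seq_len(k)) {
      piece <- substr(specs[[i]]$sequence, tx_start[j] + 1L,
                      tx_start[j] + st$el[j])
      gpos <- .map_tx_interval(st$el, st$il, pl$strand, pl$g0, tx_start[j],
                               tx_start[j] + st$el[j])
      if (pl$strand == "-") piece <- revcomp(piece)
      substr(genome[[pl$scaffold]], gpos$start[1L] + 1L, gpos$end[1L]) <-
        piece
    }
  }

  cds <- purrr::map(seq_len(n_loci), function(i) {
    if (classes[i] != "coding") {
      return(c(NA_integer_, NA_integer_))
    }
    gi <- .map_tx_interval(struct[[i]]$el, struct[[i]]$il,
                           placement[[i]]$strand, placement[[i]]$g0,
                           specs[[i]]$orf_start, specs[[i]]$orf_end)
    c(min(gi$start), max(gi$end))
  })
  models <- gene_models(
    gene_id = gene_ids,
    scaffold = scaffold_names[purrr::map_int(placement, "scaffold")],
    strand = purrr::map_chr(placement, "strand"),
    kind = ifelse(classes == "coding", "coding", "noncoding"),
    exons = exon_tabs,
    cds_start = purrr::map_int(cds, 1L),
    cds_end = purrr::map_int(cds, 2L)
  )

  transcripts <- tibble(
    id = paste0(gene_ids, ".t1"), gene_id = gene_ids,
    sequence = purrr::map_chr(specs, "sequence"),
    length = purrr::map_int(specs, "length")
  )

  # planted homology hits for pseudogene decoys
  psd <- which(classes == "pseudogene_decoy")
  hit_kind <- if (length(psd) > 0L) {
    sample(c("blastx_refseq", "pfam_hmm", "blastp_refseq"), length(psd),
           replace = TRUE, prob = c(0.6, 0.25, 0.15))
  } else character(0)
  hits <- bind_rows(purrr::map(seq_along(psd), function(j) {
    i <- psd[j]
    nh <- sample(1:3, 1L)
    ev <- if (hit_kind[j] == "pfam_hmm") 10^runif(nh, -12, -2.1)
          else 10^runif(nh, -30, 0.9)
    tibble(
      query_id = paste0(gene_ids[i], ".t1"),
      subject_id = sprintf("%s_%03d",
                           if (hit_kind[j] == "pfam_hmm") "PF" else "RefSeq",
                           sample(1:999, nh, replace = TRUE)),
      pident = round(runif(nh, 35, 95), 1),
      length = sample(30:200, nh, replace = TRUE),
      evalue = signif(ev, 3), bitscore = round(runif(nh, 40, 300), 1),
      source = hit_kind[j]
    )
  }))
  if (nrow(hits) == 0L) {
    hits <- tibble(query_id = character(), subject_id = character(),
                   pident = numeric(), length = integer(),
                   evalue = numeric(), bitscore = numeric(),
                   source = character())
  }

  truth <- .plant_truth(models, classes, gene_ids, config)
  structure(
    list(genome = genome, models = models, transcripts = transcripts,
         hits = hits, truth = truth, config = config),
    class = "linc_sim"
  )
}

# planted DE genes, modules and correlated lincRNA-neighbour pairs
.plant_truth <- function(models, classes, gene_ids, config) {
  dev_stages <- config$stages[-1L]
  coding_ids <- gene_ids[classes == "coding"]
  linc_ids <- gene_ids[classes == "lincRNA"]

  pairs <- tibble(linc_gene_id = character(), neighbor_gene_id = character())
  if (config$n_correlated_pairs > 0L && length(linc_ids) > 0L &&
      length(coding_ids) > 0L) {
    nb <- nearest_coding_neighbors(
      filter(models, .data$gene_id %in% linc_ids),
      filter(models, .data$kind == "coding")
    )
    nb <- dplyr::slice_head(arrange(group_by(nb, .data$linc_gene_id),
                                    .data$distance, .data$side), n = 1L)
    nb <- ungroup(nb)
    # one linc per neighbour so planted pairs do not share profiles
    nb <- nb[!duplicated(nb$neighbor_gene_id), ]
    take <- min(config$n_correlated_pairs, nrow(nb))
    pick <- sort(sample(nrow(nb), take))
    pairs <- select(nb[pick, ], "linc_gene_id", "neighbor_gene_id")
  }
  in_pairs <- c(pairs$linc_gene_id, pairs$neighbor_gene_id)

  modules <- tibble(gene_id = character(), module = character())
  if (config$n_modules > 0L) {
    pool_coding <- setdiff(coding_ids, in_pairs)
    pool_linc <- setdiff(linc_ids, in_pairs)
    n_linc_per <- min(round(config$module_size * 0.25),
                      length(pool_linc) %/% max(config$n_modules, 1L))
    n_cod_per <- config$module_size - n_linc_per
    need_cod <- n_cod_per * config$n_modules
    need_linc <- n_linc_per * config$n_modules
    if (need_cod > length(pool_coding) || need_linc > length(pool_linc)) {
      abort("not enough genes to plant the requested modules")
    }
    take_cod <- sample(pool_coding, need_cod)
    take_linc <- sample(pool_linc, need_linc)
    modules <- bind_rows(purrr::map(seq_len(config$n_modules), function(mm) {
      tibble(
        gene_id = c(take_cod[seq.int((mm - 1L) * n_cod_per + 1L,
                                     mm * n_cod_per)],
                    if (n_linc_per > 0L)
                      take_linc[seq.int((mm - 1L) * n_linc_per + 1L,
                                        mm * n_linc_per)]),
        module = paste0("M", mm)
      )
    }))
  }

  de <- tibble(gene_id = character(), stage = character())
  if (config$de_fraction > 0 && config$planted_fold_change != 1) {
    pool <- setdiff(c(coding_ids, linc_ids),
                    c(in_pairs, modules$gene_id))
    n_de <- round(config$de_fraction * length(pool))
    de_genes <- sort(sample(pool, n_de))
    de <- bind_rows(purrr::map(de_genes, function(g) {
      span <- sample(seq_along(dev_stages), 1L,
                     prob = c(0.35, 0.35, 0.2, rep(0.1 / max(1,
                       length(dev_stages) - 3L), max(0,
                       length(dev_stages) - 3L)))[seq_along(dev_stages)])
      first <- sample(length(dev_stages) - span + 1L, 1L)
      tibble(gene_id = g, stage = dev_stages[seq.int(first,
                                                     first + span - 1L)])
    }))
  }

  list(
    classes = tibble(gene_id = gene_ids, class = classes),
    de = de, modules = modules, pairs = pairs
  )
}

#' Simulate stage-structured counts with planted structure
#'
#' Draws negative-binomial counts for every simulated locus across all
#' libraries of the design. Gene base means are gamma-distributed; library
#' depths vary log-normally (recovered downstream as size factors). Planted
#' DE genes are shifted by the configured fold change in their planted
#' stages; planted module members share a stage profile with the configured
#' within-module correlation; planted lincRNA-neighbour pairs share a stage
#' profile exactly (proportional means).
#'
#' @param sim a `linc_sim` from [simulate_genome()].
#' @param config the same [sim_config()]; defaults to `sim$config`.
#' @return list with `counts` (tibble `gene_id` + libraries) and `design`
#'   (tibble `library`, `stage`, `replicate`).
#' @export
simulate_counts <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "linc_sim"))
  set.seed(config$seed + 1L)
  genes <- sim$truth$classes$gene_id
  n_genes <- length(genes)
  stages <- config$stages
  design <- tidyr::expand_grid(stage = stages,
                               replicate = seq_len(config$reps_per_stage))
  design <- mutate(design,
                   library = paste0(.data$stage, "_r", .data$replicate))
  design <- select(design, "library", "stage", "replicate")

  base_mean <- rgamma(n_genes, shape = 1.2, scale = 60) + 1
  names(base_mean) <- genes
  mod_tab <- sim$truth$modules
  base_mean[mod_tab$gene_id] <- runif(nrow(mod_tab), 100, 400)
  pair_genes <- unique(c(sim$truth$pairs$linc_gene_id,
                         sim$truth$pairs$neighbor_gene_id))
  base_mean[pair_genes] <- runif(length(pair_genes), 80, 300)

  offset <- matrix(0, n_genes, length(stages),
                   dimnames = list(genes, stages))
  if (nrow(sim$truth$de) > 0L) {
    idx <- cbind(match(sim$truth$de$gene_id, genes),
                 match(sim$truth$de$stage, stages))
    offset[idx] <- log2(config$planted_fold_change)
  }
  if (nrow(sim$truth$pairs) > 0L) {
    for (r in seq_len(nrow(sim$truth$pairs))) {
      v <- rnorm(length(stages), 0, 1.5)
      offset[sim$truth$pairs$linc_gene_id[r], ] <- v
      offset[sim$truth$pairs$neighbor_gene_id[r], ] <- v
    }
  }
  if (nrow(mod_tab) > 0L) {
    tau <- 2
    mods <- unique(mod_tab$module)
    # orthogonalized module profiles: planted modules are distinct
    # expression programs, so chance collinearity between profiles (likely
    # over a handful of stages) is removed by construction
    raw <- matrix(rnorm(length(stages) * length(mods)), length(stages))
    q <- qr.Q(qr(raw))[, seq_along(mods), drop = FALSE]
    profiles <- q * tau * sqrt(length(stages))
    for (mi in seq_along(mods)) {
      members <- mod_tab$gene_id[mod_tab$module == mods[mi]]
      for (g in members) {
        offset[g, ] <- sqrt(config$module_cor) * profiles[, mi] +
          sqrt(1 - config$module_cor) * rnorm(length(stages), 0, tau)
      }
    }
  }

  depth <- exp(rnorm(nrow(design), 0, config$depth_sd))
  counts <- matrix(0L, n_genes, nrow(design),
                   dimnames = list(genes, design$library))
  for (j in seq_len(nrow(design))) {
    mu <- base_mean * 2^offset[, design$stage[j]] * depth[j]
    counts[, j] <- if (config$nb_dispersion > 0) {
      rnbinom(n_genes, mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(n_genes, lambda = mu)
    }
  }
  list(counts = matrix_to_counts(counts), design = design)
}

#' Write a simulated study to disk
#'
#' Emits `genome.fa`, `transcripts.fa`, `models.gff3`, per-source hit
#' tables (`hits_blastx.tsv`, `hits_pfam.tsv`, `hits_blastp.tsv`),
#' `counts.tsv`, `design.tsv` and `truth_classes.tsv` (plus planted DE,
#' module and pair truth tables). Deterministic: identical simulations give
#' byte-identical files.
#'
#' @param sim a `linc_sim`.
#' @param dir output directory (created if missing).
#' @param counts optional result of [simulate_counts()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, counts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(g, file.path(dir, "genome.fa"), width = 70L)
  write_transcripts(sim$transcripts, file.path(dir, "transcripts.fa"))
  write_gene_models_gff3(sim$models, file.path(dir, "models.gff3"))
  for (src in hit_sources) {
    short <- c(blastx_refseq = "blastx", pfam_hmm = "pfam",
               blastp_refseq = "blastp")[[src]]
    write_hits(filter(sim$hits, .data$source == src),
               file.path(dir, paste0("hits_", short, ".tsv")))
  }
  readr::write_tsv(sim$truth$classes, file.path(dir, "truth_classes.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$de, file.path(dir, "truth_de.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$modules, file.path(dir, "truth_modules.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$pairs, file.path(dir, "truth_pairs.tsv"),
                   progress = FALSE)
  if (!is.null(counts)) {
    readr::write_tsv(counts$counts, file.path(dir, "counts.tsv"),
                     progress = FALSE)
    readr::write_tsv(counts$design, file.path(dir, "design.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}
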