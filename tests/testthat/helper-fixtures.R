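# Shared fixtures (cached per test run) and independent brute-force oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a reduced synthetic study for fast structural tests
small_config <- function(seed = 7L, ...) {
  sim_config(seed = seed, n_scaffolds = 3L, scaffold_len = 80000L,
             n_coding = 30L, n_linc = 30L, n_pseudo_decoys = 8L,
             n_overlap_decoys = 8L, n_short_decoys = 8L,
             n_modules = 0L, n_correlated_pairs = 5L, ...)
}

small_sim <- function() cached("small_sim", simulate_genome(small_config()))

small_counts <- function() cached("small_counts", simulate_counts(small_sim()))

default_sim42 <- function() {
  cached("default_sim42", simulate_genome(sim_config(seed = 42L)))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# --- independent oracles -------------------------------------------------

# codons of one frame, precomputed once per (strand, offset)
oracle_frame_codons <- function(s, off) {
  n_cod <- (nchar(s) - off) %/% 3
  if (n_cod < 1) return(character(0))
  starts <- off + 1 + 3 * (seq_len(n_cod) - 1)
  substring(s, starts, starts + 2)
}

# naive codon-walk ORF scan on both strands: every ATG is walked forward
# codon by codon until the first stop
oracle_orfs <- function(sequence) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(sequence, "")[[1]]]), collapse = "")
  out <- list()
  for (f in 1:6) {
    s <- if (f <= 3) sequence else rc
    off <- (f - 1) %% 3
    cods <- oracle_frame_codons(s, off)
    for (ci in seq_along(cods)) {
      if (cods[ci] != "ATG") next
      j <- ci
      found <- FALSE
      while (j <= length(cods)) {
        if (cods[j] %in% c("TAA", "TAG", "TGA")) { found <- TRUE; break }
        j <- j + 1
      }
      if (found) {
        i <- off + 1 + 3 * (ci - 1)
        out[[length(out) + 1]] <- data.frame(
          frame = f, start = i - 1, end = off + 3 * j,
          length_nt = off + 3 * j - (i - 1)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(frame = integer(), start = integer(),
                      end = integer(), length_nt = integer()))
  }
  df <- do.call(rbind, out)
  df <- df[df$length_nt >= 6, , drop = FALSE]
  df[order(-df$length_nt, df$frame, df$start), , drop = FALSE]
}

# codon-table translation oracle (independent of Biostrings)
oracle_translate <- function(sequence) {
  tab <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(sequence, "")[[1]]]), collapse = "")
  res <- character(6)
  for (f in 1:6) {
    s <- if (f <= 3) sequence else rc
    off <- (f - 1) %% 3
    cods <- oracle_frame_codons(s, off)
    aa <- ifelse(grepl("N", cods, fixed = TRUE), "X", unname(tab[cods]))
    res[f] <- paste(aa, collapse = "")
  }
  names(res) <- c("F1", "F2", "F3", "R1", "R2", "R3")
  res
}

# quadratic-scan interval overlap: every (exon, target) pair is compared;
# columns are extracted once so the all-pairs scan stays affordable
oracle_hits_any <- function(exons, targets) {
  e_sc <- as.character(exons$scaffold); e_s <- exons$start; e_e <- exons$end
  t_sc <- as.character(targets$scaffold); t_s <- targets$start
  t_e <- targets$end
  for (i in seq_along(e_s)) {
    hit <- e_sc[i] == t_sc & e_s[i] < t_e & t_s < e_e[i]
    if (any(hit)) return(TRUE)
  }
  FALSE
}

# brute-force nearest coding gene per side (all pairs considered), ties by
# gene id
oracle_neighbors <- function(linc_row, coding) {
  cod <- coding[coding$scaffold == linc_row$scaffold, , drop = FALSE]
  if (nrow(cod) == 0) return(NULL)
  gl <- linc_row$start - cod$end
  gr <- cod$start - linc_row$end
  overlaps <- gl < 0 & gr < 0
  sides <- ifelse(overlaps,
                  ifelse(cod$start <= linc_row$start, "upstream",
                         "downstream"),
                  ifelse(gl >= 0, "upstream", "downstream"))
  d <- ifelse(overlaps, 0L, pmax(gl, gr))
  res <- list()
  for (side in c("upstream", "downstream")) {
    in_side <- which(sides == side)
    if (length(in_side) == 0) next
    ord <- in_side[order(d[in_side], cod$gene_id[in_side])]
    res[[side]] <- data.frame(linc_gene_id = linc_row$gene_id,
                              neighbor_gene_id = cod$gene_id[ord[1]],
                              side = side,
                              distance = as.integer(d[ord[1]]))
  }
  do.call(rbind, res)
}

# random single-exon gene models on one scaffold for interval oracles
random_models <- function(n, scaffold_len, prefix, kind, coding_frac_cds = 0.6,
                          scaffold = "s1") {
  starts <- sort(sample.int(scaffold_len - 2000L, n))
  lens <- sample(200:1500, n, replace = TRUE)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  exons <- lapply(seq_len(n), function(i) {
    if (kind == "coding" && runif(1) < 0.5) {
      # two exons with an intron
      e1 <- max(100L, as.integer(lens[i] * 0.4))
      gap <- sample(100:400, 1)
      data.frame(start = c(starts[i], starts[i] + e1 + gap),
                 end = c(starts[i] + e1, starts[i] + lens[i] + gap))
    } else {
      data.frame(start = starts[i], end = starts[i] + lens[i])
    }
  })
  spans <- t(vapply(exons, function(e) c(min(e$start), max(e$end)),
                    numeric(2)))
  cds <- if (kind == "coding") {
    w <- spans[, 2] - spans[, 1]
    cs <- spans[, 1] + as.integer(w * (1 - coding_frac_cds) / 2)
    ce <- cs + as.integer(w * coding_frac_cds)
    cbind(cs, ce)
  } else {
    cbind(rep(NA_integer_, n), rep(NA_integer_, n))
  }
  gene_models(gene_id = ids, scaffold = rep(scaffold, n),
              strand = sample(c("+", "-"), n, replace = TRUE),
              kind = rep(kind, n), exons = exons,
              cds_start = cds[, 1], cds_end = cds[, 2])
}
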