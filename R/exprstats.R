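# Count tables are tibbles with a `gene_id` column followed by one column
# per library; the design is a tibble (library, stage, replicate) whose
# first stage level is the baseline (non-reproductive) condition.

counts_to_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  rownames(m) <- counts$gene_id
  m
}

matrix_to_counts <- function(m) {
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

check_design <- function(counts, design) {
  libs <- setdiff(names(counts), "gene_id")
  if (!all(libs %in% design$library)) {
    abort("every count column must map to a design row")
  }
  design[match(libs, design$library), , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each library, the median over genes with positive geometric mean of
#' the ratio of the library's count to the gene's geometric mean across
#' libraries (the median-of-ratios normalization of count-based DE
#' analysis).
#'
#' @param counts count tibble (`gene_id` + one column per library).
#' @return tibble `library`, `size_factor`.
#' @export
size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  if (ncol(m) < 1L || nrow(m) < 1L) abort("empty count matrix")
  log_gm <- rowMeans(log(m))
  use <- is.finite(log_gm)
  if (!any(use)) {
    warn("no gene with positive counts in all libraries; using per-library positive subset")
    sf <- apply(m, 2L, function(col) {
      pos <- col > 0
      median(col[pos] / exp(rowMeans(log(m[pos, , drop = FALSE] + 0.5))))
    })
  } else {
    sf <- apply(m, 2L, function(col) {
      median(exp(log(col[use]) - log_gm[use]))
    })
  }
  if (any(!is.finite(sf)) || any(sf <= 0)) abort("non-positive size factor")
  tibble(library = colnames(m), size_factor = unname(sf))
}

#' Log-normalized counts
#'
#' Elementwise `log2(count / size_factor + 1)`.
#'
#' @param counts count tibble.
#' @param sf size-factor tibble from [size_factors()]; computed if missing.
#' @return tibble of the same shape as `counts`.
#' @export
normalize_log <- function(counts, sf = size_factors(counts)) {
  m <- counts_to_matrix(counts)
  s <- sf$size_factor[match(colnames(m), sf$library)]
  if (anyNA(s)) abort("size factor missing for some library")
  matrix_to_counts(log2(sweep(m, 2L, s, "/") + 1))
}

#' Sample PCA on the most variable genes
#'
#' Centred (unscaled) principal components of the libraries, computed on the
#' `top_n` genes with highest variance. The sign of each component is fixed
#' so that its largest-magnitude gene loading is positive.
#'
#' @param norm log-normalized tibble from [normalize_log()].
#' @param top_n number of most-variable genes to use (default 500).
#' @return object of class `linc_pca`: list with `coords` (tibble `library`,
#'   `PC1`, ...), `var_frac`, `loadings`, `genes_used`.
#' @export
pca_samples <- function(norm, top_n = 500L) {
  m <- counts_to_matrix(norm)
  if (ncol(m) < 2L) abort("PCA needs at least 2 libraries")
  v <- apply(m, 1L, var)
  if (top_n > nrow(m)) {
    warn(sprintf("top_n = %d exceeds gene count %d; using all genes",
                 top_n, nrow(m)))
    top_n <- nrow(m)
  }
  keep <- order(v, decreasing = TRUE)[seq_len(top_n)]
  pc <- prcomp(t(m[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  coords <- bind_cols(tibble(library = colnames(m)), as_tibble(pc$x))
  structure(
    list(coords = coords, var_frac = pc$sdev^2 / sum(pc$sdev^2),
         loadings = pc$rotation, genes_used = rownames(m)[keep]),
    class = "linc_pca"
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment preserving input order (thin validated wrapper
#' around [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test for one gene
#'
#' Two-group comparison (stage vs baseline) under an NB model with
#' size-factor offsets. Group means are total-count over total-size-factor;
#' the gene dispersion is a pooled within-group method-of-moments estimate
#' on normalized counts (floored at 1e-8); the Wald statistic is the log2
#' fold change over its delta-method standard error, referred to the normal
#' distribution.
#'
#' @param counts_a,counts_b raw counts of the gene in the stage and baseline
#'   libraries.
#' @param sf_a,sf_b matching size factors.
#' @return one-row tibble: `base_mean`, `log2_fold_change`, `se`, `wald_z`,
#'   `p`, `dispersion`, `degenerate`.
#' @export
nb_wald_test <- function(counts_a, counts_b, sf_a, sf_b) {
  stopifnot(length(counts_a) == length(sf_a),
            length(counts_b) == length(sf_b),
            length(counts_a) >= 2L, length(counts_b) >= 2L)
  if (all(counts_a == 0) && all(counts_b == 0)) {
    return(tibble(base_mean = 0, log2_fold_change = 0, se = NA_real_,
                  wald_z = 0, p = 1, dispersion = NA_real_,
                  degenerate = TRUE))
  }
  q_a <- counts_a / sf_a
  q_b <- counts_b / sf_b
  disp_part <- function(q, sf) {
    qb <- mean(q)
    if (qb <= 0) return(NA_real_)
    (var(q) - qb * mean(1 / sf)) / qb^2
  }
  parts <- c(disp_part(q_a, sf_a), disp_part(q_b, sf_b))
  disp <- max(1e-8, mean(parts, na.rm = TRUE))
  if (!is.finite(disp)) disp <- 1e-8
  mu_a <- (sum(counts_a) + 0.5) / sum(sf_a)
  mu_b <- (sum(counts_b) + 0.5) / sum(sf_b)
  lfc <- log2(mu_a) - log2(mu_b)
  var_log2 <- function(mu, sf) {
    sum(sf * mu + disp * sf^2 * mu^2) / (sum(sf)^2 * mu^2 * log(2)^2)
  }
  # small-sample correction for the plug-in dispersion: with d residual
  # degrees of freedom the naive Wald z is t_d-like, so the SE is scaled by
  # sqrt(d / (d - 2)) before referring z to the normal distribution
  d <- length(counts_a) + length(counts_b) - 2L
  infl <- if (d > 2L) sqrt(d / (d - 2)) else sqrt(2)
  se <- infl * sqrt(var_log2(mu_a, sf_a) + var_log2(mu_b, sf_b))
  z <- lfc / se
  tibble(base_mean = mean(c(q_a, q_b)), log2_fold_change = lfc, se = se,
         wald_z = z, p = 2 * pnorm(-abs(z)), dispersion = disp,
         degenerate = FALSE)
}

#' Per-stage differential expression versus the baseline condition
#'
#' Runs [nb_wald_test()] for every gene in every non-baseline stage against
#' the baseline (first stage of the design, the non-reproductive condition),
#' with BH adjustment within each stage contrast. Upregulation calls use
#' `p_adj < alpha` and positive log2 fold change.
#'
#' @param counts raw count tibble.
#' @param design design tibble (`library`, `stage`, `replicate`); the first
#'   `stage` value (or level) is the baseline.
#' @param alpha BH-adjusted significance threshold (default 0.1).
#' @param sf optional precomputed size factors.
#' @return object of class `linc_de`: list with `table` (tibble `gene_id`,
#'   `stage`, `base_mean`, `log2_fold_change`, `se`, `wald_z`, `p`, `p_adj`,
#'   `upregulated`, `degenerate`), `baseline`, `alpha`.
#' @export
de_test <- function(counts, design, alpha = 0.1, sf = NULL) {
  design <- check_design(counts, design)
  stages <- if (is.factor(design$stage)) levels(design$stage)
            else unique(design$stage)
  baseline <- stages[[1L]]
  if (length(stages) < 2L) abort("need at least two stages")
  if (is.null(sf)) sf <- size_factors(counts)
  m <- counts_to_matrix(counts)
  s <- sf$size_factor[match(colnames(m), sf$library)]
  stage_of <- as.character(design$stage)
  base_idx <- which(stage_of == baseline)
  if (length(base_idx) < 2L) abort("baseline needs >= 2 libraries")
  res <- purrr::map(setdiff(stages, baseline), function(st) {
    idx <- which(stage_of == st)
    if (length(idx) < 2L) abort(sprintf("stage '%s' needs >= 2 libraries", st))
    rows <- purrr::map(seq_len(nrow(m)), function(g) {
      nb_wald_test(m[g, idx], m[g, base_idx], s[idx], s[base_idx])
    })
    tab <- bind_rows(rows)
    tab$gene_id <- rownames(m)
    tab$stage <- st
    tab$p_adj <- bh_adjust(tab$p)
    tab
  })
  tab <- bind_rows(res)
  tab$upregulated <- tab$p_adj < alpha & tab$log2_fold_change > 0
  structure(
    list(table = relocate(tab, "gene_id", "stage"), baseline = baseline,
         alpha = alpha),
    class = "linc_de"
  )
}

#' Per-stage upregulated gene sets and cross-stage tallies
#'
#' @param de a `linc_de` object or its `table`.
#' @return object of class `linc_stage_sets`: list with `sets` (named list
#'   of gene-id vectors), `summary` (tibble `stage`, `n_upregulated`,
#'   `n_unique`), `shared_all` (ids upregulated in every stage) and
#'   `any_stage` (ids upregulated in at least one stage).
#' @export
stage_upregulated_sets <- function(de) {
  tab <- if (inherits(de, "linc_de")) de$table else de
  stages <- unique(tab$stage)
  sets <- purrr::map(setNames(stages, stages), function(st) {
    sort(tab$gene_id[tab$stage == st & tab$upregulated])
  })
  any_stage <- sort(unique(unlist(sets)))
  shared_all <- sort(Reduce(intersect, sets))
  uniq <- purrr::imap_int(sets, function(s, st) {
    others <- unlist(sets[setdiff(names(sets), st)])
    sum(!s %in% others)
  })
  structure(
    list(sets = sets,
         summary = tibble(stage = names(sets),
                          n_upregulated = unname(lengths(sets)),
                          n_unique = unname(uniq)),
         shared_all = shared_all, any_stage = any_stage),
    class = "linc_stage_sets"
  )
}

# Spearman rho with average ranks, plus a p-value by t-approximation or
# exact permutation enumeration
spearman_test <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (method == "exact") {
    if (n > 9L) abort("exact permutation p only for n <= 9")
    perms <- .permutations(n)
    rhos <- apply(perms, 1L, function(pm) cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(abs(rho), 1 - 1e-12)
    tstat <- r2 * sqrt((n - 2) / (1 - r2^2))
    p <- 2 * pt(-tstat, df = n - 2)
  }
  list(rho = rho, p = p)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, purrr::map(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Neighbour-correlation independence filter
#'
#' Tests each lincRNA/nearest-coding-neighbour pair for Spearman correlation
#' of their log-normalized expression across all libraries; BH adjustment is
#' applied jointly over all tested pairs. A lincRNA is discarded when any of
#' its pairs has `rho >= rho_cut` and adjusted p below `alpha` — such
#' lincRNAs are likely co-regulated with (or misassembled fragments of)
#' their neighbour rather than independently regulated.
#'
#' @param norm log-normalized tibble covering lincRNA and coding genes.
#' @param pairs neighbour-pair tibble from [nearest_coding_neighbors()].
#' @param rho_cut correlation threshold (default 0.6).
#' @param alpha BH-adjusted p threshold (default 0.05).
#' @param p_method `"t"` (default) or `"exact"` permutation (n <= 9).
#' @return list with `pairs` (input plus `rho`, `p`, `p_adj`, `correlated`,
#'   `skipped`), `independent` and `discarded` lincRNA gene-id vectors.
#' @export
independence_filter <- function(norm, pairs, rho_cut = 0.6, alpha = 0.05,
                                p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  m <- counts_to_matrix(norm)
  missing <- setdiff(unique(c(pairs$linc_gene_id, pairs$neighbor_gene_id)),
                     rownames(m))
  if (length(missing) > 0L) {
    abort(sprintf("pair references unknown gene(s): %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  stats <- purrr::map2(pairs$linc_gene_id, pairs$neighbor_gene_id,
                       function(a, b) {
    spearman_test(m[a, ], m[b, ], method = p_method)
  })
  out <- mutate(pairs,
                rho = purrr::map_dbl(stats, "rho"),
                p = purrr::map_dbl(stats, "p"),
                skipped = is.na(.data$rho))
  if (any(out$skipped)) {
    warn(sprintf("%d pair(s) with constant profile skipped",
                 sum(out$skipped)))
  }
  out$p_adj <- NA_real_
  out$p_adj[!out$skipped] <- bh_adjust(out$p[!out$skipped])
  out$correlated <- !out$skipped & out$rho >= rho_cut & out$p_adj < alpha
  lincs <- unique(pairs$linc_gene_id)
  disc <- unique(out$linc_gene_id[out$correlated])
  list(pairs = out, independent = sort(setdiff(lincs, disc)),
       discarded = sort(disc))
}

#' Stage clustering by shared upregulated genes
#'
#' Distance between two stages is 1 minus the Jaccard index of their
#' upregulated gene sets (0 when both are empty); stages are clustered by
#' average-linkage hierarchical clustering with stage-name tie-breaking via
#' deterministic input order.
#'
#' @param sets a `linc_stage_sets` object or named list of gene-id vectors.
#' @return object of class `linc_stage_clust`: list with `dist` (matrix) and
#'   `hclust`.
#' @export
de_overlap_clustering <- function(sets) {
  if (inherits(sets, "linc_stage_sets")) sets <- sets$sets
  stopifnot(length(sets) >= 2L)
  sets <- sets[order(names(sets))]
  k <- length(sets)
  d <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      un <- length(union(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <-
        if (un == 0L) 0 else 1 - length(intersect(sets[[i]], sets[[j]])) / un
    }
  }
  hc <- hclust(as.dist(d), method = "average")
  structure(list(dist = d, hclust = hc), class = "linc_stage_clust")
}

#' Export a stage dendrogram as Newick
#'
#' @param clust a `linc_stage_clust` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stage_newick <- function(clust, path) {
  ape::write.tree(ape::as.phylo(clust$hclust), file = path)
  invisible(path)
}

#' Candidate genes for in situ hybridization
#'
#' A gene qualifies when its maximum normalized count over libraries reaches
#' `min_count` and the ratio of its highest to lowest per-stage mean
#' normalized count (with a pseudocount of 1) reaches `min_fold` — the
#' operational definition of "robustly detectable and strongly
#' stage-modulated".
#'
#' @param counts raw count tibble.
#' @param design design tibble.
#' @param min_count minimum normalized count in at least one library
#'   (default 40).
#' @param min_fold minimum fold difference between any two stage means
#'   (default 20).
#' @param sf optional precomputed size factors.
#' @return tibble `gene_id`, `max_count`, `stage_fold`, `candidate`.
#' @export
ish_candidates <- function(counts, design, min_count = 40, min_fold = 20,
                           sf = NULL) {
  design <- check_design(counts, design)
  if (is.null(sf)) sf <- size_factors(counts)
  m <- counts_to_matrix(counts)
  s <- sf$size_factor[match(colnames(m), sf$library)]
  normed <- sweep(m, 2L, s, "/")
  stage_of <- as.character(design$stage)
  stage_means <- vapply(unique(stage_of), function(st) {
    rowMeans(normed[, stage_of == st, drop = FALSE])
  }, numeric(nrow(m)))
  if (!is.matrix(stage_means)) {
    stage_means <- matrix(stage_means, nrow = nrow(m))
  }
  max_count <- unname(apply(normed, 1L, max))
  fold <- unname((apply(stage_means, 1L, max) + 1) /
                   (apply(stage_means, 1L, min) + 1))
  tibble(gene_id = rownames(m), max_count = max_count, stage_fold = fold,
         candidate = max_count >= min_count & fold >= min_fold)
}
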