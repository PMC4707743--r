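#' Expression and variance filter for co-expression analysis
#'
#' Keeps genes with normalized counts above `min_count` in at least
#' `min_samples` libraries, then keeps those whose variance of
#' `log2(x + 1)` normalized counts lies at or above the `var_quantile`
#' quantile of the survivors' variance distribution (default: top 75%).
#'
#' @param counts raw count tibble.
#' @param sf optional precomputed size factors.
#' @param min_count normalized-count threshold (default 5).
#' @param min_samples library threshold (default 3).
#' @param var_quantile variance quantile cut (default 0.25).
#' @return character vector of retained gene ids.
#' @export
expression_filter <- function(counts, sf = NULL, min_count = 5,
                              min_samples = 3L, var_quantile = 0.25) {
  if (is.null(sf)) sf <- size_factors(counts)
  m <- counts_to_matrix(counts)
  s <- sf$size_factor[match(colnames(m), sf$library)]
  normed <- sweep(m, 2L, s, "/")
  expressed <- rowSums(normed > min_count) >= min_samples
  lg <- log2(normed[expressed, , drop = FALSE] + 1)
  if (nrow(lg) == 0L) return(character(0))
  v <- apply(lg, 1L, var)
  rownames(m)[expressed][v >= quantile(v, var_quantile)]
}

#' Soft-thresholded correlation adjacency
#'
#' Entrywise `|pearson(x_i, x_j)|^beta` between gene expression profiles
#' (unsigned network); the diagonal is set to 0 so that connectivity
#' excludes self-adjacency. With `signed = TRUE`, adjacency is
#' `((1 + cor)/2)^beta`.
#'
#' @param norm log-normalized tibble restricted to the analysis genes.
#' @param beta soft-thresholding power (default 18).
#' @param signed use the signed transform (default unsigned).
#' @return symmetric adjacency matrix with genes as dimnames and attribute
#'   `beta`.
#' @export
adjacency <- function(norm, beta = 18L, signed = FALSE) {
  m <- counts_to_matrix(norm)
  if (ncol(m) < 3L) abort("need at least 3 libraries")
  csd <- apply(m, 1L, sd)
  if (any(csd == 0)) {
    abort(sprintf("constant expression row(s): %s",
                  paste(head(rownames(m)[csd == 0], 5L), collapse = ", ")))
  }
  cc <- cor(t(m))
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  a
}

#' Topological overlap matrix
#'
#' Standard unsigned topological overlap: for i != j,
#' \deqn{t_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'                     {\min(k_i, k_j) + 1 - a_{ij}}}
#' with connectivity \eqn{k_i = \sum_{u \ne i} a_{iu}} and \eqn{t_{ii} = 1}.
#'
#' @param A adjacency matrix from [adjacency()] (zero diagonal).
#' @return symmetric TOM with unit diagonal.
#' @export
tom <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A < 0 | A > 1)) abort("adjacency entries must lie in [0, 1]")
  if (any(diag(A) != 0)) abort("adjacency diagonal must be zero")
  k <- rowSums(A)
  shared <- A %*% A  # a_ii = 0, so this is the sum over u != i, j
  denom <- outer(k, k, pmin) + 1 - A
  stopifnot(all(denom > 0))
  tm <- (shared + A) / denom
  diag(tm) <- 1
  dimnames(tm) <- dimnames(A)
  (tm + t(tm)) / 2
}

.module_letters <- function(k) {
  if (k <= 26L) return(LETTERS[seq_len(k)])
  c(LETTERS, as.vector(outer(LETTERS, LETTERS,
                             function(a, b) paste0(a, b))))[seq_len(k)]
}

# leaves and height per internal node of an hclust tree
.hclust_nodes <- function(hc) {
  n <- length(hc$order)
  leaves <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    leaves[[k]] <- c(
      if (kids[1] < 0) -kids[1] else integer(0),
      if (kids[1] > 0) leaves[[kids[1]]] else integer(0),
      if (kids[2] < 0) -kids[2] else integer(0),
      if (kids[2] > 0) leaves[[kids[2]]] else integer(0)
    )
  }
  leaves
}

#' Module detection by dynamic tree cut on the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on dissimilarity `1 - T`,
#' followed by a basic dynamic cut: cut heights are scanned downward from
#' 0.99 until at least two clusters of `min_module_size` or more emerge;
#' each resulting branch is then recursively split where the gap between a
#' node's height and its tallest child exceeds `split_gap` of the node
#' height and both children hold `min_module_size` leaves. Clusters below
#' the minimum size are pooled as `unassigned`; modules are lettered
#' `A`, `B`, ... in decreasing size.
#'
#' @param tom_matrix topological overlap matrix from [tom()].
#' @param min_module_size minimum module size (default 30).
#' @param split_gap branch-splitting gap fraction (default 0.25).
#' @return object of class `linc_modules`: list with `assignment` (tibble
#'   `gene_id`, `module`), `sizes`, `hclust`, `cut_height`, `params`.
#' @export
cluster_modules <- function(tom_matrix, min_module_size = 30L,
                            split_gap = 0.25) {
  genes <- rownames(tom_matrix) %||% paste0("g", seq_len(nrow(tom_matrix)))
  n <- nrow(tom_matrix)
  if (n < min_module_size) {
    warn("fewer genes than min_module_size; everything unassigned")
    return(.modules_result(tibble(gene_id = genes, module = "unassigned"),
                           NULL, NA_real_, min_module_size, split_gap))
  }
  hc <- hclust(as.dist(1 - tom_matrix), method = "average")
  node_leaves <- .hclust_nodes(hc)
  node_height <- hc$height

  # adaptive scan: candidate cuts are midpoints between consecutive merge
  # heights, scanned from the top; the highest cut maximizing the number of
  # clusters meeting min_module_size is chosen (soft powers compress TOM
  # dissimilarities towards 1, so a fixed grid would miss branches)
  hs <- sort(unique(hc$height), decreasing = TRUE)
  mids <- (hs + c(hs[-1L], 0)) / 2
  best <- list(h = NA_real_, big = 0L)
  for (h in mids) {
    cl <- cutree(hc, h = h)
    big <- sum(table(cl) >= min_module_size)
    if (big > best$big) best <- list(h = h, big = big)
  }
  chosen <- best$h

  module_of <- rep("unassigned", n)
  if (!is.na(chosen)) {
    cl <- cutree(hc, h = chosen)
    # top node of each cluster: the highest merge entirely within it
    clusters <- purrr::map(split(seq_len(n), cl), identity)
    split_node <- function(members) {
      if (length(members) < 2L) return(list(members))
      within <- which(purrr::map_lgl(node_leaves, function(lv) {
        length(lv) <= length(members) && all(lv %in% members)
      }))
      root <- within[which.max(node_height[within])]
      recurse <- function(node) {
        kids <- hc$merge[node, ]
        kid_sets <- purrr::map(kids, function(kd) {
          if (kd < 0) -kd else node_leaves[[kd]]
        })
        kid_h <- purrr::map_dbl(kids, function(kd) {
          if (kd < 0) 0 else node_height[kd]
        })
        gap <- node_height[node] - max(kid_h)
        if (gap > split_gap * node_height[node] &&
            all(lengths(kid_sets) >= min_module_size)) {
          c(
            if (kids[1] > 0) recurse(kids[1]) else kid_sets[1],
            if (kids[2] > 0) recurse(kids[2]) else kid_sets[2]
          )
        } else {
          list(node_leaves[[node]])
        }
      }
      recurse(root)
    }
    final <- purrr::flatten(purrr::map(clusters, split_node))
    final <- final[lengths(final) >= min_module_size]
    if (length(final) > 0L) {
      ord <- order(-lengths(final),
                   purrr::map_int(final, min))  # size, then leftmost gene
      labels <- .module_letters(length(final))
      for (i in seq_along(ord)) {
        module_of[final[[ord[i]]]] <- labels[i]
      }
    }
  }
  .modules_result(tibble(gene_id = genes, module = module_of), hc, chosen,
                  min_module_size, split_gap)
}

.modules_result <- function(assignment, hc, cut_height, min_module_size,
                            split_gap) {
  sizes <- arrange(dplyr::count(assignment, .data$module, name = "n_genes"),
                   .data$module)
  structure(
    list(assignment = assignment, sizes = sizes, hclust = hc,
         cut_height = cut_height,
         params = list(min_module_size = min_module_size,
                       split_gap = split_gap)),
    class = "linc_modules"
  )
}

#' Per-module per-stage median expression profiles
#'
#' Entry (module, stage) is the median over the module's genes of the mean
#' normalized expression across the stage's libraries.
#'
#' @param modules a `linc_modules` object or assignment tibble.
#' @param norm log-normalized tibble.
#' @param design design tibble.
#' @param include_unassigned include the `unassigned` pool (default FALSE).
#' @return tibble `module`, `stage`, `median_expr`.
#' @export
module_profiles <- function(modules, norm, design,
                            include_unassigned = FALSE) {
  assignment <- if (inherits(modules, "linc_modules")) modules$assignment
                else modules
  design <- check_design(norm, design)
  m <- counts_to_matrix(norm)
  stage_of <- as.character(design$stage)
  stages <- unique(stage_of)
  stage_means <- vapply(stages, function(st) {
    rowMeans(m[, stage_of == st, drop = FALSE])
  }, numeric(nrow(m)))
  if (!is.matrix(stage_means)) {
    stage_means <- matrix(stage_means, nrow = nrow(m),
                          dimnames = list(rownames(m), stages))
  }
  keep <- assignment$module != "unassigned" | include_unassigned
  assignment <- assignment[keep & assignment$gene_id %in% rownames(m), ]
  rows <- purrr::map(split(assignment$gene_id, assignment$module),
                     function(gids) {
    apply(stage_means[gids, , drop = FALSE], 2L, median)
  })
  out <- purrr::imap(rows, function(v, mod) {
    tibble(module = mod, stage = stages, median_expr = unname(v[stages]))
  })
  bind_rows(out)
}

#' Term enrichment of a module by one-sided Fisher exact tests
#'
#' For each term annotating at least one background gene, tests enrichment
#' of the term among the module's genes against the background with a
#' one-sided (greater) Fisher exact test; BH adjustment across terms.
#'
#' @param module_genes character vector of module gene ids.
#' @param background character vector of background gene ids (superset of
#'   the module).
#' @param annotation tibble with columns `gene_id`, `term`.
#' @param alpha adjusted-p threshold for the `enriched` flag (default 0.05).
#' @return tibble `term`, `n_module_term`, `n_module`, `n_bg_term`, `n_bg`,
#'   `odds_ratio`, `p`, `p_adj`, `enriched`, sorted by `p`.
#' @export
term_enrichment <- function(module_genes, background, annotation,
                            alpha = 0.05) {
  if (!all(module_genes %in% background)) {
    abort("module genes must be a subset of the background")
  }
  annotation <- filter(annotation, .data$gene_id %in% background)
  terms <- unique(annotation$term)
  n_bg <- length(unique(background))
  n_mod <- length(unique(module_genes))
  rows <- purrr::map(terms, function(tm) {
    with_term <- unique(annotation$gene_id[annotation$term == tm])
    a <- sum(module_genes %in% with_term)
    b <- n_mod - a
    c_ <- length(setdiff(with_term, module_genes))
    d <- n_bg - n_mod - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                      alternative = "greater")
    tibble(term = tm, n_module_term = a, n_module = n_mod,
           n_bg_term = length(with_term), n_bg = n_bg,
           odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(term = character(), n_module_term = integer(),
                  n_module = integer(), n_bg_term = integer(),
                  n_bg = integer(), odds_ratio = numeric(), p = numeric(),
                  p_adj = numeric(), enriched = logical()))
  }
  out$p_adj <- bh_adjust(out$p)
  out$enriched <- out$p_adj < alpha
  arrange(out, .data$p)
}
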