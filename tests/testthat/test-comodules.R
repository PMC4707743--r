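norm_tbl <- function(m) {
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), out)
  out
}

test_that("expression filter applies both predicates with boundary care", {
  libs <- paste0("L", 1:6)
  m <- rbind(
    two_libs = c(10, 10, 0, 0, 0, 0),      # expressed in only 2 libraries
    three_libs = c(10, 10, 10, 0, 0, 0),
    high_var = c(100, 2, 80, 3, 90, 1),
    flat = c(6, 6, 6, 6, 6, 6)
  )
  colnames(m) <- libs
  sf <- tibble::tibble(library = libs, size_factor = rep(1, 6))
  kept <- expression_filter(norm_tbl(m), sf = sf, var_quantile = 0)
  expect_false("two_libs" %in% kept)
  expect_true(all(c("three_libs", "high_var") %in% kept))

  # all equal variances: quantile ties keep everything
  eq <- rbind(a = c(10, 20, 10, 20, 10, 20), b = c(20, 10, 20, 10, 20, 10),
              c = c(10, 20, 10, 20, 10, 20))
  colnames(eq) <- libs
  expect_setequal(expression_filter(norm_tbl(eq), sf = sf), c("a", "b", "c"))

  # brute-force predicate oracle on a random matrix
  set.seed(31)
  r <- matrix(rnbinom(3000, mu = 12, size = 1), 500, 6,
              dimnames = list(paste0("g", 1:500), libs))
  got <- expression_filter(norm_tbl(r), sf = sf)
  expressed <- rowSums(r > 5) >= 3
  lv <- apply(log2(r[expressed, ] + 1), 1, var)
  want <- names(lv)[lv >= quantile(lv, 0.25)]
  expect_setequal(got, want)
})

test_that("adjacency is |cor|^beta with fixed points at 0 and 1", {
  libs <- paste0("L", 1:8)
  x <- rnorm(8)
  m <- rbind(a = x, b = 2 * x + 3, c = rnorm(8))
  colnames(m) <- libs
  A <- adjacency(norm_tbl(m), beta = 7)
  expect_equal(A["a", "b"], 1)
  expect_equal(diag(A), c(a = 0, b = 0, c = 0))
  # formula oracle to 1e-12
  set.seed(5)
  r <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("L", 1:10)))
  A18 <- adjacency(norm_tbl(r), beta = 18)
  for (i in 1:20) for (j in 1:20) {
    want <- if (i == j) 0 else abs(cor(r[i, ], r[j, ]))^18
    expect_equal(A18[i, j], want, tolerance = 1e-12)
  }
  # raising beta weakly sparsifies
  A6 <- adjacency(norm_tbl(r), beta = 6)
  expect_true(all(A18 <= A6 + 1e-12))
  # constant row is an error naming the gene
  bad <- rbind(m, flatgene = rep(1, 8))
  expect_error(adjacency(norm_tbl(bad)), "flatgene")
})

test_that("TOM matches closed forms and the triple-loop oracle", {
  # 2-gene network: t12 = a
  for (a in c(0.2, 0.5, 0.9)) {
    A <- matrix(c(0, a, a, 0), 2)
    expect_equal(tom(A)[1, 2], a, tolerance = 1e-12)
  }
  # empty network
  Z <- matrix(0, 4, 4)
  expect_equal(tom(Z)[upper.tri(Z)], rep(0, 6))
  # random instances vs brute force
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    A <- matrix(runif(n * n), n)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    tm <- tom(A)
    k <- rowSums(A)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) {
        expect_equal(tm[i, j], 1)
      } else {
        s <- 0
        for (u in seq_len(n)) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
        want <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
        expect_equal(tm[i, j], want, tolerance = 1e-12)
      }
    }
    expect_equal(tm, t(tm))
    expect_true(all(tm >= 0 & tm <= 1 + 1e-12))
  }
})

test_that("block-diagonal similarity yields exactly the planted modules", {
  set.seed(34)
  libs <- paste0("L", 1:10)
  x1 <- rnorm(10); x2 <- rnorm(10)
  m <- rbind(
    do.call(rbind, replicate(35, x1 * runif(1, 0.5, 2), simplify = FALSE)),
    do.call(rbind, replicate(35, x2 * runif(1, 0.5, 2), simplify = FALSE))
  )
  rownames(m) <- paste0("g", 1:70)
  colnames(m) <- libs
  A <- abs(cor(t(m)))^6
  diag(A) <- 0
  res <- cluster_modules(tom(A), min_module_size = 30)
  expect_equal(sum(res$sizes$module != "unassigned"), 2L)
  mods <- res$assignment$module
  expect_equal(length(unique(mods[1:35])), 1L)
  expect_equal(length(unique(mods[36:70])), 1L)
  expect_false(mods[1] == mods[36])
  # labels ordered by decreasing size: equal here, so A and B both present
  expect_setequal(unique(mods), c("A", "B"))
})

test_that("structureless networks leave everything unassigned", {
  Z <- matrix(0, 50, 50, dimnames = list(paste0("g", 1:50),
                                         paste0("g", 1:50)))
  res <- cluster_modules(tom(Z), min_module_size = 30)
  expect_true(all(res$assignment$module == "unassigned"))
  expect_warning(cluster_modules(tom(Z[1:10, 1:10])), "fewer genes")
})

test_that("module detection is deterministic and permutation-equivalent", {
  cts <- cached("mod_counts", {
    cfg <- sim_config(seed = 11)
    sim <- cached("mod_sim", simulate_genome(sim_config(seed = 11)))
    simulate_counts(sim, cfg)
  })
  sim <- cached("mod_sim", NULL)
  mod_genes <- sim$truth$modules$gene_id
  norm <- normalize_log(cts$counts)
  sub <- dplyr::filter(norm, gene_id %in% mod_genes)
  tm <- tom(adjacency(sub, beta = 18))
  r1 <- cluster_modules(tm)
  r2 <- cluster_modules(tm)
  expect_identical(r1$assignment, r2$assignment)
  perm <- sample(nrow(tm))
  r3 <- cluster_modules(tm[perm, perm])
  joined <- dplyr::inner_join(r1$assignment, r3$assignment, by = "gene_id")
  # same partition up to label names
  tab <- table(joined$module.x, joined$module.y)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("module profiles are medians of stage means", {
  libs <- c("n1", "n2", "v1", "v2")
  design <- tibble::tibble(library = libs, stage = c("non", "non", "vit",
                                                     "vit"),
                           replicate = c(1L, 2L, 1L, 2L))
  m <- rbind(g1 = c(1, 3, 10, 12), g2 = c(5, 5, 2, 2), g3 = c(0, 0, 7, 7))
  colnames(m) <- libs
  assign <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                           module = c("A", "A", "B"))
  prof <- module_profiles(assign, norm_tbl(m), design)
  expect_equal(prof$median_expr[prof$module == "A" & prof$stage == "non"],
               median(c(2, 5)))
  expect_equal(prof$median_expr[prof$module == "A" & prof$stage == "vit"],
               median(c(11, 2)))
  # single-gene module equals that gene's stage means
  expect_equal(prof$median_expr[prof$module == "B"], c(0, 7))
  # constant matrix: flat profiles
  flat <- matrix(4, 3, 4, dimnames = list(c("g1", "g2", "g3"), libs))
  pf <- module_profiles(assign, norm_tbl(flat), design)
  expect_true(all(pf$median_expr == 4))
  # brute-force median-of-means oracle on random input
  set.seed(35)
  r <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), libs))
  ra <- tibble::tibble(gene_id = rownames(r),
                       module = sample(c("A", "B"), 10, replace = TRUE))
  pr <- module_profiles(ra, norm_tbl(r), design)
  for (i in seq_len(nrow(pr))) {
    gids <- ra$gene_id[ra$module == pr$module[i]]
    cols <- design$library[design$stage == pr$stage[i]]
    expect_equal(pr$median_expr[i],
                 median(apply(r[gids, cols, drop = FALSE], 1, mean)))
  }
})

test_that("enrichment p-values equal the hypergeometric tail", {
  bg <- paste0("g", 1:40)
  mod <- paste0("g", 1:20)
  ann <- tibble::tibble(gene_id = mod, term = "t1")  # all module genes
  res <- term_enrichment(mod, bg, ann)
  # direct hypergeometric summation: P(X >= 20) drawing 20 from 20/40
  want <- sum(dhyper(20:20, 20, 20, 20))
  expect_equal(res$p, want, tolerance = 1e-12)
  expect_true(res$enriched)
  # term absent from module, rare in background: not enriched
  ann2 <- tibble::tibble(gene_id = c("g39", "g40"), term = "t2")
  res2 <- term_enrichment(mod, bg, ann2)
  expect_gte(res2$p, 0.05)
  # random-module null calibration
  set.seed(13)
  bg2 <- paste0("g", 1:200)
  ann3 <- tibble::tibble(
    gene_id = sample(bg2, 600, replace = TRUE),
    term = sample(paste0("t", 1:12), 600, replace = TRUE)
  )
  ann3 <- dplyr::distinct(ann3)
  hits <- replicate(300, {
    mg <- sample(bg2, 30)
    mean(term_enrichment(mg, bg2, ann3)$p < 0.05)
  })
  expect_lt(mean(hits), 0.1)  # near-nominal false positive rate
  # module must be inside the background
  expect_error(term_enrichment(c("zz"), bg, ann), "subset")
})
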