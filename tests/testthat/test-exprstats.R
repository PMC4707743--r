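toy_counts <- function(m) {
  tibble::as_tibble(cbind(
    data.frame(gene_id = paste0("g", seq_len(nrow(m)))),
    as.data.frame(m)
  ))
}

test_that("size factors obey identity, scale equivariance and the formula", {
  set.seed(21)
  m <- matrix(rpois(300, 50) + 1, 50, 6,
              dimnames = list(NULL, paste0("L", 1:6)))
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("L", 1:3)
  sf_same <- size_factors(toy_counts(same))
  expect_equal(sf_same$size_factor, rep(1, 3))

  doubled <- m
  doubled[, 2] <- m[, 1] * 2
  sf <- size_factors(toy_counts(doubled))
  expect_equal(sf$size_factor[2] / sf$size_factor[1], 2, tolerance = 1e-12)

  # direct formula evaluation
  want <- apply(m, 2, function(col) {
    gm <- exp(rowMeans(log(m)))
    median(col / gm)
  })
  expect_equal(size_factors(toy_counts(m))$size_factor, unname(want))
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  set.seed(22)
  m <- matrix(rnbinom(606, mu = 80, size = 5) + 1, 101, 6,
              dimnames = list(paste0("g", 1:101), paste0("L", 1:6)))
  got <- size_factors(toy_counts(m))$size_factor
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(m))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("log normalization is the stated elementwise transform", {
  m <- matrix(c(0, 4, 8, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  sf <- tibble::tibble(library = c("a", "b"), size_factor = c(2, 2))
  norm <- normalize_log(toy_counts(m), sf)
  expect_equal(unname(as.matrix(norm[, -1])), unname(log2(m / 2 + 1)))
  expect_equal(norm[[2]][1], 0)          # zero count -> 0
  expect_equal(log2(2 / 2 + 1), 1)       # count = sf -> 1
  set.seed(23)
  r <- matrix(rpois(60, 20), 10, 6, dimnames = list(NULL, paste0("L", 1:6)))
  sfr <- size_factors(toy_counts(r))
  got <- as.matrix(normalize_log(toy_counts(r), sfr)[, -1])
  want <- log2(sweep(r, 2, sfr$size_factor, "/") + 1)
  expect_equal(unname(got), unname(want))
})

test_that("sample PCA has spectral properties and matches eigen-analysis", {
  set.seed(24)
  m <- matrix(rnorm(600, 8, 1), 100, 6,
              dimnames = list(paste0("g", 1:100),
                              c(paste0("A", 1:3), paste0("B", 1:3))))
  # one planted separating gene dominating variance
  m["g1", ] <- c(2, 2, 2, 14, 14, 14) + rnorm(6, 0, 0.01)
  pc <- pca_samples(toy_counts(m), top_n = 50)
  expect_true(all(diff(pc$var_frac) <= 1e-12))
  expect_lte(sum(pc$var_frac), 1 + 1e-12)
  # PC1 separates the two groups
  pc1 <- pc$coords$PC1
  expect_true(max(pc1[1:3]) < min(pc1[4:6]) ||
                min(pc1[1:3]) > max(pc1[4:6]))
  # variance fraction matches an independent eigen-decomposition
  v <- apply(m, 1, var)
  top <- m[order(v, decreasing = TRUE)[1:50], ]
  x <- scale(t(top), center = TRUE, scale = FALSE)
  ev <- eigen(cov(x))$values
  expect_equal(pc$var_frac[1], ev[1] / sum(ev), tolerance = 1e-10)
  # duplicated library: identical coordinates
  dup <- m[, c(1:6, 1)]
  colnames(dup) <- c(colnames(m), "A1bis")
  pcd <- pca_samples(toy_counts(dup), top_n = 50)
  expect_equal(unlist(pcd$coords[7, -1]), unlist(pcd$coords[1, -1]))
  expect_warning(pca_samples(toy_counts(m), top_n = 1000), "using all")
})

test_that("NB Wald test handles degenerate inputs", {
  res0 <- nb_wald_test(c(0, 0, 0), c(0, 0, 0), rep(1, 3), rep(1, 3))
  expect_equal(res0$p, 1)
  expect_equal(res0$log2_fold_change, 0)
  expect_true(res0$degenerate)
  # identical groups, near-zero dispersion: z near 0, p near 1
  res <- nb_wald_test(c(100, 100, 100), c(100, 100, 100), rep(1, 3),
                      rep(1, 3))
  expect_equal(res$log2_fold_change, 0)
  expect_equal(res$p, 1, tolerance = 1e-6)
})

test_that("BH adjustment equals the direct step-up formula", {
  expect_equal(bh_adjust(0.42), 0.42)
  p <- c(0.01, 0.02, 0.03, 0.04)
  want <- vapply(seq_along(p), function(i) {
    min(vapply(i:4, function(k) 4 * sort(p)[k] / k, numeric(1)))
  }, numeric(1))[rank(p)]
  expect_equal(bh_adjust(p), want)
  set.seed(25)
  q <- runif(200)
  direct <- vapply(seq_along(q), function(i) {
    r <- rank(q)[i]
    min(1, min(vapply(which(rank(q) >= r), function(j) {
      length(q) * q[j] / rank(q)[j]
    }, numeric(1))))
  }, numeric(1))
  expect_equal(bh_adjust(q), direct, tolerance = 1e-12)
  expect_lte(max(bh_adjust(q)), 1)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("stage DE wiring plants and recovers upregulation calls", {
  cts <- small_counts()
  de <- de_test(cts$counts, cts$design)
  expect_s3_class(de, "linc_de")
  expect_equal(de$baseline, "nonreproductive")
  tab <- tidy(de)
  expect_true(all(tab$upregulated ==
                    (tab$p_adj < 0.1 & tab$log2_fold_change > 0)))
  # planted upregulated genes are mostly recovered in their stages
  truth <- small_sim()$truth$de
  hit <- dplyr::inner_join(truth, tab, by = c("gene_id", "stage"))
  expect_gte(mean(hit$upregulated), 0.7)
})

test_that("stage set tallies equal exhaustive set arithmetic", {
  sets <- list(s1 = c("a", "b", "c"), s2 = c("b", "c", "d"),
               s3 = c("c", "e"))
  fake <- tibble::tibble(
    gene_id = unlist(sets),
    stage = rep(names(sets), lengths(sets)),
    upregulated = TRUE
  )
  res <- stage_upregulated_sets(fake)
  expect_equal(res$shared_all, "c")
  expect_setequal(res$any_stage, c("a", "b", "c", "d", "e"))
  expect_equal(res$summary$n_upregulated, c(3L, 3L, 2L))
  expect_equal(res$summary$n_unique, c(1L, 1L, 1L))  # a, d, e
  # no gene significant: all sets empty
  empty <- stage_upregulated_sets(
    tibble::tibble(gene_id = "g", stage = c("s1", "s2"),
                   upregulated = FALSE))
  expect_equal(lengths(empty$sets), c(s1 = 0L, s2 = 0L))
  expect_equal(length(empty$shared_all), 0L)
})

test_that("Spearman rho matches rank-then-Pearson to 1e-12", {
  set.seed(3)
  for (rep in 1:50) {
    x <- rnorm(24)
    y <- 0.5 * x + rnorm(24)
    st <- spearman_test(x, y)
    expect_equal(st$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  # ties handled by average ranks
  x <- c(1, 1, 2, 3, 3, 4)
  y <- c(2, 1, 1, 3, 4, 4)
  expect_equal(spearman_test(x, y)$rho, cor(rank(x), rank(y)),
               tolerance = 1e-12)
  # monotone transform invariance
  z <- rnorm(15)
  expect_equal(spearman_test(exp(z), z)$rho, 1)
  # exact permutation p for small n agrees with enumeration-free bounds
  ex <- spearman_test(1:5, c(2, 1, 3, 5, 4), method = "exact")
  tt <- spearman_test(1:5, c(2, 1, 3, 5, 4), method = "t")
  expect_gte(ex$p, 0)
  expect_lte(ex$p, 1)
  expect_equal(ex$rho, tt$rho)
})

test_that("independence filter discards correlated neighbours only", {
  set.seed(26)
  libs <- paste0("L", 1:12)
  base <- rnorm(12, 6, 2)
  m <- rbind(
    linc1 = base, cod1 = base,                     # rho = 1
    linc2 = rnorm(12, 6, 2), cod2 = rnorm(12, 6, 2),
    linc3 = rnorm(12, 6, 2), cod3 = rnorm(12, 6, 2)
  )
  colnames(m) <- libs
  norm <- toy_counts(m)
  norm$gene_id <- rownames(m)
  pairs <- tibble::tibble(
    linc_gene_id = c("linc1", "linc2", "linc3"),
    neighbor_gene_id = c("cod1", "cod2", "cod3"),
    side = "upstream", distance = 100L
  )
  res <- independence_filter(norm, pairs)
  expect_equal(res$discarded, "linc1")
  expect_setequal(res$independent, c("linc2", "linc3"))
  expect_equal(res$pairs$rho[1], 1)
  # scaling a neighbour's profile leaves rho unchanged
  m2 <- m
  m2["cod1", ] <- m["cod1", ] * 7.3
  norm2 <- toy_counts(m2)
  norm2$gene_id <- rownames(m2)
  res2 <- independence_filter(norm2, pairs)
  expect_equal(res2$pairs$rho, res$pairs$rho)
  # constant profile: pair skipped with warning
  m3 <- m
  m3["cod2", ] <- 4
  norm3 <- toy_counts(m3)
  norm3$gene_id <- rownames(m3)
  expect_warning(res3 <- independence_filter(norm3, pairs), "constant")
  expect_true(res3$pairs$skipped[2])
})

test_that("a strong correlated pair (rho ~ 0.68) is discarded", {
  set.seed(27)
  # construct profiles whose Spearman rho is exactly 0.68 by rank design
  n <- 25
  x <- 1:n
  repeat {
    y <- x + sample(-8:8, n, replace = TRUE)
    if (abs(cor(rank(x), rank(y)) - 0.68) < 0.02) break
  }
  m <- rbind(linc1 = as.numeric(x), cod1 = as.numeric(y))
  colnames(m) <- paste0("L", 1:n)
  norm <- toy_counts(m)
  norm$gene_id <- rownames(m)
  pairs <- tibble::tibble(linc_gene_id = "linc1",
                          neighbor_gene_id = "cod1",
                          side = "upstream", distance = 10L)
  res <- independence_filter(norm, pairs)
  expect_gte(res$pairs$rho, 0.6)
  expect_lt(res$pairs$p_adj, 0.05)
  expect_equal(res$discarded, "linc1")
})

test_that("rho thresholds 0.59/0.61 fall on the documented side", {
  # deterministic rank vectors with rho just below / above 0.6
  find_y <- function(target) {
    set.seed(28)
    n <- 21
    repeat {
      y <- sample(n)
      r <- cor(rank(1:n), rank(y))
      if (abs(r - target) < 0.005) return(y)
    }
  }
  for (target in c(0.59, 0.61)) {
    y <- find_y(target)
    m <- rbind(linc1 = as.numeric(1:21), cod1 = as.numeric(y))
    colnames(m) <- paste0("L", 1:21)
    norm <- toy_counts(m)
    norm$gene_id <- rownames(m)
    pairs <- tibble::tibble(linc_gene_id = "linc1",
                            neighbor_gene_id = "cod1",
                            side = "upstream", distance = 10L)
    res <- independence_filter(norm, pairs)
    if (target < 0.6) {
      expect_equal(res$discarded, character(0))
    } else {
      expect_equal(res$discarded, "linc1")
    }
  }
})

test_that("stage distances are 1 - Jaccard with correct extremes", {
  sets <- list(a = c("x", "y"), b = c("x", "y"), c = c("p", "q"))
  res <- de_overlap_clustering(sets)
  expect_equal(res$dist["a", "b"], 0)
  expect_equal(res$dist["a", "c"], 1)
  # both empty: distance 0
  res2 <- de_overlap_clustering(list(a = character(0), b = character(0)))
  expect_equal(res2$dist["a", "b"], 0)
  # random sets: full matrix equals brute-force Jaccard; triangle inequality
  set.seed(29)
  rs <- lapply(1:5, function(i) sample(letters, sample(3:12, 1)))
  names(rs) <- paste0("s", 1:5)
  d <- de_overlap_clustering(rs)$dist
  for (i in 1:5) for (j in 1:5) {
    a <- rs[[rownames(d)[i]]]; b <- rs[[colnames(d)[j]]]
    want <- if (i == j) 0 else 1 - length(intersect(a, b)) /
      length(union(a, b))
    expect_equal(d[i, j], want)
  }
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
  }
  # newick export round-trips through ape
  path <- withr::local_tempfile(fileext = ".nwk")
  write_stage_newick(de_overlap_clustering(rs), path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, names(rs))
})

test_that("ISH candidate rules enforce both predicates at their boundaries", {
  design <- tibble::tibble(
    library = c("n1", "n2", "v1", "v2"),
    stage = c("non", "non", "vit", "vit"), replicate = c(1L, 2L, 1L, 2L)
  )
  m <- rbind(
    just_below = c(0, 0, 39.9, 39.9),   # max < 40: fails
    at_forty = c(0, 0, 40, 40),         # max = 40, fold > 20: passes
    constant = c(50, 50, 50, 50),       # no stage variation: fails
    strong = c(1, 1, 300, 300)
  )
  colnames(m) <- design$library
  cts <- toy_counts(m)
  cts$gene_id <- rownames(m)
  sf <- tibble::tibble(library = design$library, size_factor = rep(1, 4))
  res <- ish_candidates(cts, design, sf = sf)
  expect_equal(res$candidate,
               c(FALSE, TRUE, FALSE, TRUE))
  # brute-force predicate evaluation on a random matrix
  set.seed(30)
  r <- matrix(rnbinom(400, mu = 30, size = 1), 100, 4,
              dimnames = list(paste0("g", 1:100), design$library))
  rc <- toy_counts(r)
  rc$gene_id <- rownames(r)
  got <- ish_candidates(rc, design, sf = sf)
  want <- vapply(seq_len(nrow(r)), function(i) {
    means <- c(mean(r[i, 1:2]), mean(r[i, 3:4]))
    max(r[i, ]) >= 40 && (max(means) + 1) / (min(means) + 1) >= 20
  }, logical(1))
  expect_equal(got$candidate, want)
})
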