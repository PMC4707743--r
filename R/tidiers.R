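#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x a `linc_de` object.
#' @param ... unused.
#' @return the per-gene, per-stage result tibble.
#' @export
tidy.linc_de <- function(x, ...) x$table

#' One-row summary of a differential-expression result
#'
#' @param x a `linc_de` object.
#' @param ... unused.
#' @return tibble with gene/stage counts and the number of upregulation
#'   calls.
#' @export
glance.linc_de <- function(x, ...) {
  tibble(
    n_genes = dplyr::n_distinct(x$table$gene_id),
    n_stages = dplyr::n_distinct(x$table$stage),
    baseline = x$baseline, alpha = x$alpha,
    n_upregulated_calls = sum(x$table$upregulated),
    n_genes_upregulated = dplyr::n_distinct(
      x$table$gene_id[x$table$upregulated])
  )
}

#' Tidy a module assignment
#'
#' @param x a `linc_modules` object.
#' @param ... unused.
#' @return tibble `gene_id`, `module`.
#' @export
tidy.linc_modules <- function(x, ...) x$assignment

#' One-row summary of a module assignment
#'
#' @param x a `linc_modules` object.
#' @param ... unused.
#' @return tibble with module count and size summaries.
#' @export
glance.linc_modules <- function(x, ...) {
  real <- filter(x$sizes, .data$module != "unassigned")
  tibble(
    n_modules = nrow(real),
    n_genes_assigned = sum(real$n_genes),
    n_unassigned = sum(x$sizes$n_genes) - sum(real$n_genes),
    largest_module = if (nrow(real) > 0L) max(real$n_genes) else 0L,
    cut_height = x$cut_height
  )
}

#' Tidy a sample PCA
#'
#' @param x a `linc_pca` object.
#' @param ... unused.
#' @return tibble of per-library coordinates.
#' @export
tidy.linc_pca <- function(x, ...) x$coords

#' One-row summary of a sample PCA
#'
#' @param x a `linc_pca` object.
#' @param ... unused.
#' @return tibble with leading variance fractions and gene count used.
#' @export
glance.linc_pca <- function(x, ...) {
  tibble(
    n_genes = length(x$genes_used),
    pc1_var = x$var_frac[1L],
    pc2_var = if (length(x$var_frac) >= 2L) x$var_frac[2L] else NA_real_
  )
}

#' @export
print.linc_de <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<linc_de> %d genes x %d stages vs '%s'; %d genes upregulated (BH p < %g)\n",
    g$n_genes, g$n_stages, g$baseline, g$n_genes_upregulated, x$alpha))
  invisible(x)
}

#' @export
print.linc_modules <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<linc_modules> %d modules, %d genes assigned, %d unassigned\n",
              g$n_modules, g$n_genes_assigned, g$n_unassigned))
  invisible(x)
}

#' @export
print.linc_sim <- function(x, ...) {
  cls <- table(x$truth$classes$class)
  cat(sprintf("<linc_sim> %d scaffolds, %d loci (%s)\n",
              length(x$genome), nrow(x$models),
              paste(names(cls), cls, sep = ": ", collapse = ", ")))
  invisible(x)
}
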