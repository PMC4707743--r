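.pipeline_defaults <- list(
  # inputs
  transcripts = NULL, hits_blastx = NULL, hits_pfam = NULL,
  hits_blastp = NULL, models = NULL, counts = NULL, design = NULL,
  annotation = NULL, out_dir = NULL,
  # thresholds (defaults are the standard values of this kind of screen)
  min_orf = 300L, min_nc_len = 600L, evalue_blastx = 10,
  evalue_pfam = 0.01, evalue_blastp = 10, cp_threshold = 1,
  rho_cut = 0.6, alpha_independence = 0.05, alpha_de = 0.1,
  min_count = 5, min_samples = 3L, var_quantile = 0.25, beta = 18L,
  min_module_size = 30L, ish_min_count = 40, ish_min_fold = 20,
  strict_exon_overlap = FALSE, seed = 1L
)

#' Pipeline configuration
#'
#' Input paths and every stage threshold in one place. Threshold defaults
#' are the screen's standard values (ORF 300 nt, non-coding minimum
#' 600 nt, e-value gates 10 / 0.01 / 10, coding potential 1, rho 0.6 with
#' BH p < 0.05, DE BH p < 0.1, module filter counts > 5 in >= 3 samples and
#' variance top 75%, soft power 18, module minimum 30, ISH 40 counts and
#' 20-fold). Any non-default value is reported when the pipeline runs.
#'
#' @param ... named overrides of the defaults; unknown names are an error.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(.pipeline_defaults))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(.pipeline_defaults, overrides, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments;
#'   unknown keys are an error.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Configuration for a written simulation directory
#'
#' Convenience constructor pointing all input paths of [pipeline_config()]
#' at the files emitted by [write_simulation()].
#'
#' @param sim_dir directory written by [write_simulation()].
#' @param out_dir pipeline output directory.
#' @param ... further [pipeline_config()] overrides.
#' @return list of class `pipeline_config`.
#' @export
simulation_pipeline_config <- function(sim_dir, out_dir, ...) {
  pipeline_config(
    transcripts = file.path(sim_dir, "transcripts.fa"),
    hits_blastx = file.path(sim_dir, "hits_blastx.tsv"),
    hits_pfam = file.path(sim_dir, "hits_pfam.tsv"),
    hits_blastp = file.path(sim_dir, "hits_blastp.tsv"),
    models = file.path(sim_dir, "models.gff3"),
    counts = file.path(sim_dir, "counts.tsv"),
    design = file.path(sim_dir, "design.tsv"),
    out_dir = out_dir, ...
  )
}

.read_counts_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' Run the full lincRNA discovery and expression pipeline
#'
#' Executes, in order: transcript classification cascade; intergenic filter
#' against coding gene models; nearest-neighbour search and expression
#' independence filter; per-stage differential expression versus the
#' baseline condition; ISH candidate selection; co-expression module
#' detection on DE-upregulated coding genes plus independent lincRNAs; and
#' (when an annotation is supplied) per-module term enrichment. Per-stage
#' tables are written under `config$out_dir`; re-running with the same
#' configuration and inputs reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the run manifest, invisibly: list with `funnel` (tibble of
#'   per-stage counts), `params` (tibble) and the per-stage result objects
#'   in `results`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  for (key in c("transcripts", "models", "counts", "design", "out_dir")) {
    if (is.null(config[[key]])) {
      abort(sprintf("pipeline config is missing required path '%s'", key))
    }
  }
  set.seed(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  non_default <- names(.pipeline_defaults)[
    !purrr::map2_lgl(.pipeline_defaults, unclass(config)[
      names(.pipeline_defaults)], identical)
  ]
  non_default <- setdiff(non_default,
                         c("transcripts", "hits_blastx", "hits_pfam",
                           "hits_blastp", "models", "counts", "design",
                           "annotation", "out_dir"))
  for (key in non_default) {
    say("parameter override: %s = %s (default %s)", key,
        format(config[[key]]), format(.pipeline_defaults[[key]]))
  }

  transcripts <- read_transcripts(config$transcripts)
  hits <- bind_rows(
    if (!is.null(config$hits_blastx))
      read_hits(config$hits_blastx, "blastx_refseq"),
    if (!is.null(config$hits_pfam)) read_hits(config$hits_pfam, "pfam_hmm"),
    if (!is.null(config$hits_blastp))
      read_hits(config$hits_blastp, "blastp_refseq")
  )
  models <- read_gene_models_gff3(config$models)
  counts <- .read_counts_tsv(config$counts)
  design <- readr::read_tsv(config$design, col_types = "cci",
                            progress = FALSE)

  say("classify: %d transcripts", nrow(transcripts))
  decisions <- classify_transcripts(
    transcripts, hits, cp_threshold = config$cp_threshold,
    min_orf = config$min_orf, min_nc_len = config$min_nc_len,
    evalue_blastx = config$evalue_blastx, evalue_pfam = config$evalue_pfam,
    evalue_blastp = config$evalue_blastp
  )
  readr::write_tsv(decisions, file.path(config$out_dir, "classification.tsv"),
                   progress = FALSE)
  cand_genes <- unique(decisions$gene_id[
    decisions$label == "lncRNA_candidate"])
  coding_models <- filter(models, .data$kind == "coding")
  cand_models <- filter(models, .data$gene_id %in% cand_genes)

  say("intergenic filter: %d candidates vs %d coding genes",
      nrow(cand_models), nrow(coding_models))
  ig <- intergenic_filter(cand_models, coding_models,
                          strict_exon_overlap = config$strict_exon_overlap)
  readr::write_tsv(ig$decisions,
                   file.path(config$out_dir, "intergenic_filter.tsv"),
                   progress = FALSE)
  linc_models <- ig$lincRNA

  sf <- size_factors(counts)
  norm <- normalize_log(counts, sf)
  readr::write_tsv(sf, file.path(config$out_dir, "size_factors.tsv"),
                   progress = FALSE)

  say("independence filter: %d lincRNAs", nrow(linc_models))
  nb_pairs <- nearest_coding_neighbors(linc_models, coding_models)
  nb_pairs <- filter(nb_pairs, .data$neighbor_gene_id %in% counts$gene_id,
                     .data$linc_gene_id %in% counts$gene_id)
  indep <- independence_filter(norm, nb_pairs, rho_cut = config$rho_cut,
                               alpha = config$alpha_independence)
  # lincRNAs with no same-scaffold neighbour are trivially independent
  indep_lincs <- sort(union(indep$independent,
                            setdiff(linc_models$gene_id,
                                    nb_pairs$linc_gene_id)))
  readr::write_tsv(indep$pairs,
                   file.path(config$out_dir, "neighbor_pairs.tsv"),
                   progress = FALSE)

  say("differential expression: %d genes", nrow(counts))
  de <- de_test(counts, design, alpha = config$alpha_de, sf = sf)
  readr::write_tsv(de$table, file.path(config$out_dir, "de_results.tsv"),
                   progress = FALSE)
  linc_de <- stage_upregulated_sets(
    filter(de$table, .data$gene_id %in% indep_lincs))
  coding_de <- stage_upregulated_sets(
    filter(de$table, .data$gene_id %in% coding_models$gene_id))
  up_lincs <- linc_de$any_stage
  clust <- NULL
  if (length(linc_de$sets) >= 2L) {
    clust <- de_overlap_clustering(linc_de)
    readr::write_tsv(as_tibble(clust$dist, rownames = "stage"),
                     file.path(config$out_dir, "stage_distance.tsv"),
                     progress = FALSE)
    write_stage_newick(clust,
                       file.path(config$out_dir, "stage_dendrogram.nwk"))
  }

  ish <- ish_candidates(
    filter(counts, .data$gene_id %in% linc_models$gene_id), design,
    min_count = config$ish_min_count, min_fold = config$ish_min_fold,
    sf = sf
  )
  readr::write_tsv(ish, file.path(config$out_dir, "ish_candidates.tsv"),
                   progress = FALSE)

  universe <- union(coding_de$any_stage, indep_lincs)
  say("modules: universe of %d genes", length(universe))
  kept <- expression_filter(
    filter(counts, .data$gene_id %in% universe), sf = sf,
    min_count = config$min_count, min_samples = config$min_samples,
    var_quantile = config$var_quantile
  )
  modules <- NULL
  profiles <- tibble(module = character(), stage = character(),
                     median_expr = numeric())
  if (length(kept) >= 3L) {
    A <- adjacency(filter(norm, .data$gene_id %in% kept),
                   beta = config$beta)
    modules <- cluster_modules(tom(A),
                               min_module_size = config$min_module_size)
    readr::write_tsv(modules$assignment,
                     file.path(config$out_dir, "modules.tsv"),
                     progress = FALSE)
    profiles <- module_profiles(modules, norm, design)
    readr::write_tsv(profiles,
                     file.path(config$out_dir, "module_profiles.tsv"),
                     progress = FALSE)
  }

  enrichment <- NULL
  if (!is.null(config$annotation) && !is.null(modules)) {
    annotation <- readr::read_tsv(config$annotation, col_types = "cc",
                                  progress = FALSE)
    mods <- setdiff(unique(modules$assignment$module), "unassigned")
    enrichment <- bind_rows(purrr::map(mods, function(mm) {
      genes <- modules$assignment$gene_id[modules$assignment$module == mm]
      mutate(term_enrichment(genes, kept, annotation), module = mm)
    }))
    readr::write_tsv(enrichment,
                     file.path(config$out_dir, "enrichment.tsv"),
                     progress = FALSE)
  }

  n_modules <- if (is.null(modules)) 0L else
    sum(modules$sizes$module != "unassigned")
  in_modules <- if (is.null(modules)) 0L else
    sum(modules$assignment$module != "unassigned")
  funnel <- tibble(
    stage = c("input_transcripts", "coding", "lncRNA_candidates",
              "lincRNAs", "independent_lincRNAs", "upregulated_lincRNAs",
              "ish_candidates", "module_universe", "module_genes_kept",
              "genes_in_modules", "modules"),
    n = c(nrow(transcripts), sum(decisions$label == "coding"),
          length(cand_genes), nrow(linc_models), length(indep_lincs),
          length(up_lincs), sum(ish$candidate), length(universe),
          length(kept), in_modules, n_modules)
  )
  param_names <- setdiff(names(.pipeline_defaults),
                         c("transcripts", "hits_blastx", "hits_pfam",
                           "hits_blastp", "models", "counts", "design",
                           "annotation", "out_dir"))
  params <- tibble(
    parameter = param_names,
    value = purrr::map_chr(param_names, ~ format(config[[.x]]))
  )
  readr::write_tsv(funnel, file.path(config$out_dir, "manifest_funnel.tsv"),
                   progress = FALSE)
  readr::write_tsv(params, file.path(config$out_dir, "manifest_params.tsv"),
                   progress = FALSE)
  say("done: %d lincRNAs, %d independent, %d upregulated, %d modules",
      nrow(linc_models), length(indep_lincs), length(up_lincs), n_modules)
  invisible(list(
    funnel = funnel, params = params,
    results = list(decisions = decisions, intergenic = ig,
                   neighbor_pairs = indep, de = de,
                   linc_sets = linc_de, coding_sets = coding_de,
                   stage_clust = clust, ish = ish, modules = modules,
                   profiles = profiles, enrichment = enrichment,
                   independent_lincs = indep_lincs)
  ))
}
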