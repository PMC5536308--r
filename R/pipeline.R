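## End-to-end orchestration: a single configuration drives synthetic-data
## generation (or file inputs), per-mutant proteomics and transcriptomics
## DE, overlap permutation tests (transcripts, proteins, GO terms), GO
## enrichment per ontology and class profiling, with a uniform output
## layout and a machine-readable run manifest.

#' Pipeline configuration
#'
#' @param inputs either a [sim_config()] (synthetic branch) or a named list
#'   of file paths: `protein_groups`, `counts`, `samples`, `dag`,
#'   `annotations`, `classes`.
#' @param protein_fc,protein_p protein DE thresholds.
#' @param transcript_fc,transcript_q transcript DE thresholds.
#' @param go_min_log2_cpm expression filter for GO-input transcripts.
#' @param node_size,elim_cutoff GO elim parameters.
#' @param go_p GO-term significance threshold used for the term-overlap
#'   permutation test.
#' @param iterations permutation iterations (default 10000).
#' @param universe_mode overlap universe mode, see [venn_regions()].
#' @param seed global seed; each stage derives a child seed from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs,
                            protein_fc = 1.5, protein_p = 0.05,
                            transcript_fc = 1.5, transcript_q = 0.01,
                            go_min_log2_cpm = 8,
                            node_size = 10, elim_cutoff = 0.01, go_p = 0.05,
                            iterations = 10000,
                            universe_mode = "intersection",
                            seed = 1) {
  if (iterations < 1) stop_fmt("iterations must be at least 1")
  for (v in c(protein_fc, protein_p, transcript_fc, transcript_q))
    if (v <= 0) stop_fmt("thresholds must be positive")
  synthetic <- inherits(inputs, "sim_config")
  if (!synthetic) {
    req <- c("protein_groups", "counts", "samples", "dag", "annotations",
             "classes")
    missing <- setdiff(req, names(inputs))
    if (length(missing))
      stop_fmt("input paths missing and no synthetic block given: %s",
               paste(missing, collapse = ", "))
  }
  structure(list(inputs = inputs, synthetic = synthetic,
                 protein_fc = protein_fc, protein_p = protein_p,
                 transcript_fc = transcript_fc, transcript_q = transcript_q,
                 go_min_log2_cpm = go_min_log2_cpm, node_size = node_size,
                 elim_cutoff = elim_cutoff, go_p = go_p,
                 iterations = as.integer(iterations),
                 universe_mode = universe_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the [pipeline_config()] fields; a `synthetic` block
#' is interpreted as [sim_config()] arguments, otherwise an `inputs` block
#' of file paths is required.
#'
#' @param path YAML file path.
#' @param seed,iterations optional overrides.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL, iterations = NULL) {
  y <- yaml::read_yaml(path)
  inputs <- if (!is.null(y$synthetic)) {
    sc <- y$synthetic
    if (!is.null(sc$class_proportions))
      sc$class_proportions <- unlist(sc$class_proportions)
    if (!is.null(sc$de_fraction)) sc$de_fraction <- unlist(sc$de_fraction)
    if (!is.null(sc$overlap_spec)) sc$overlap_spec <- unlist(sc$overlap_spec)
    if (!is.null(sc$lib_size_range)) sc$lib_size_range <- unlist(sc$lib_size_range)
    do.call(sim_config, sc)
  } else y$inputs
  args <- y[setdiff(names(y), c("synthetic", "inputs"))]
  args$inputs <- inputs
  if (!is.null(seed)) args$seed <- seed
  if (!is.null(iterations)) args$iterations <- iterations
  do.call(pipeline_config, args)
}

#' Run the full multi-omics pipeline
#'
#' Per mutant condition: protein and transcript DE tables; across mutants:
#' overlap permutation tables for transcripts, protein groups and
#' significant GO terms; per mutant and ontology: GO elim results; per
#' mutant: class-profile summaries and cross-omics correlations. All tables
#' are written as TSV with threshold provenance in `#` header comments,
#' plus a JSON run manifest. Outputs are deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param quiet suppress stage log messages to stderr.
#' @return invisibly, a list with every result table and the manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## ---- load or simulate inputs -------------------------------------------
  if (config$synthetic) {
    log_stage("[simulate] generating synthetic inputs")
    sim <- simulate_experiment(config$inputs)
    in_dir <- file.path(out_dir, "inputs")
    write_sim_inputs(sim, in_dir)
    pg_path <- file.path(in_dir, "proteinGroups.txt")
    counts <- sim$counts; samples <- sim$samples
    dag_edges <- sim$dag; annotations <- sim$annotations
    classes <- sim$classes
    reference <- config$inputs$reference
    conditions <- config$inputs$conditions
  } else {
    log_stage("[load] reading inputs")
    pg_path <- config$inputs$protein_groups
    cm <- read_tsv_plain(config$inputs$counts)
    counts <- as.matrix(cm[, -1, drop = FALSE])
    rownames(counts) <- cm[[1]]
    storage.mode(counts) <- "integer"
    samples <- read_tsv_plain(config$inputs$samples)
    dag_edges <- read_tsv_plain(config$inputs$dag)
    annotations <- read_tsv_plain(config$inputs$annotations)
    classes <- read_tsv_plain(config$inputs$classes)
    reference <- config$inputs$reference %||% "wt"
    conditions <- setdiff(unique(samples$condition), reference)
  }
  thr_hdr <- sprintf(
    "thresholds: protein |FC|>%g p<%g; transcript |FC|>%g q<%g; GO log2CPM>%g nodeSize=%d elim=%g; iterations=%d; universe=%s; seed=%d",
    config$protein_fc, config$protein_p, config$transcript_fc,
    config$transcript_q, config$go_min_log2_cpm, config$node_size,
    config$elim_cutoff, config$iterations, config$universe_mode, config$seed)

  ## ---- per-mutant DE ------------------------------------------------------
  rt <- read_protein_groups(pg_path)
  prot <- list(); trans <- list()
  for (mut in conditions) {
    log_stage("[proteomics] %s vs %s", mut, reference)
    prot[[mut]] <- silac_de(rt, mutant = mut, wt = reference,
                            fc_cutoff = config$protein_fc,
                            p_cutoff = config$protein_p)
    write_tsv_commented(prot[[mut]],
                        file.path(out_dir, sprintf("proteins_%s.tsv", mut)),
                        thr_hdr)
    log_stage("[rnaseq] %s vs %s", mut, reference)
    trans[[mut]] <- rnaseq_de(counts, samples, mutant = mut, wt = reference,
                              fc = config$transcript_fc,
                              q = config$transcript_q,
                              min_log2_cpm = config$go_min_log2_cpm)
    write_tsv_commented(trans[[mut]],
                        file.path(out_dir, sprintf("transcripts_%s.tsv", mut)),
                        thr_hdr)
  }

  ## ---- GO enrichment ------------------------------------------------------
  log_stage("[go] elim enrichment")
  ann_f <- filter_evidence(annotations)
  ontologies <- unique(if ("ontology" %in% names(dag_edges) &&
                           nrow(dag_edges)) dag_edges$ontology else "all")
  go_res <- list()
  for (ont in ontologies) {
    edges <- if ("ontology" %in% names(dag_edges))
      dag_edges[dag_edges$ontology == ont, , drop = FALSE] else dag_edges
    dag <- go_dag(edges)
    ann_p <- propagate_annotations(dag, ann_f)
    for (mut in conditions) {
      tr <- trans[[mut]]
      universe <- tr$gene_id
      interesting <- tr$gene_id[tr$go_eligible %||% tr$is_de]
      res <- elim_enrichment(dag, ann_p, universe, interesting,
                             node_size = config$node_size,
                             elim_cutoff = config$elim_cutoff)
      go_res[[ont]][[mut]] <- res
      write_tsv_commented(res,
                          file.path(out_dir, sprintf("go_%s_%s.tsv", ont, mut)),
                          thr_hdr)
    }
  }

  ## ---- overlap permutation tests -----------------------------------------
  overlaps <- list()
  if (length(conditions) >= 2) {
    log_stage("[overlap] permutation tests (B = %d)", config$iterations)
    ov_in <- overlap_input(
      lapply(trans, function(x) x$gene_id),
      lapply(trans, function(x) x$gene_id[x$is_de]))
    overlaps$transcripts <- permutation_null(
      ov_in, B = config$iterations, seed = child_seed(config$seed, 11L),
      universe_mode = config$universe_mode)
    ov_in <- overlap_input(
      lapply(prot, function(x) x$protein_group_id),
      lapply(prot, function(x) x$protein_group_id[x$is_de]))
    overlaps$proteins <- permutation_null(
      ov_in, B = config$iterations, seed = child_seed(config$seed, 12L),
      universe_mode = config$universe_mode)
    for (ont in ontologies) {
      ov_in <- overlap_input(
        lapply(go_res[[ont]], function(x) x$term),
        lapply(go_res[[ont]], function(x)
          x$term[x$p_fisher_two_tailed < config$go_p]))
      overlaps[[paste0("go_", ont)]] <- permutation_null(
        ov_in, B = config$iterations,
        seed = child_seed(config$seed, 13L + match(ont, ontologies)),
        universe_mode = config$universe_mode)
    }
    for (nm in names(overlaps))
      write_tsv_commented(overlaps[[nm]],
                          file.path(out_dir, sprintf("overlap_%s.tsv", nm)),
                          thr_hdr)
  }

  ## ---- class profiles -----------------------------------------------------
  log_stage("[classes] distribution and enrichment profiles")
  class_map <- stats::setNames(classes$class, classes$gene)
  class_rows <- list(); corr_rows <- list()
  for (mut in conditions) {
    tr <- trans[[mut]]
    lab <- class_map[tr$gene_id]
    for (cl in c("oogenic", "spermatogenic")) {
      kt <- ks_class_test(tr$log2fc_mean, lab, cl)
      class_rows[[paste(mut, cl, "ks")]] <-
        data.frame(mutant = mut, class = cl, statistic = "ks_D",
                   value = kt$D, p_value = kt$p_value,
                   stringsAsFactors = FALSE)
    }
    for (dir in c("over", "under")) {
      en <- obs_exp_enrichment(lab, tr$direction, dir)
      class_rows[[paste(mut, dir, "enrich")]] <-
        data.frame(mutant = mut, class = en$class,
                   statistic = paste0("log2_obs_over_exp_", dir),
                   value = en$log2_obs_over_exp,
                   p_value = en$p_fisher_two_tailed,
                   stringsAsFactors = FALSE)
    }
    corr <- omics_correlation(prot[[mut]], tr)
    corr$mutant <- mut
    corr_rows[[mut]] <- corr[, c("mutant", "category", "n", "pearson_r")]
  }
  class_summary <- do.call(rbind, class_rows)
  rownames(class_summary) <- NULL
  corr_summary <- do.call(rbind, corr_rows)
  rownames(corr_summary) <- NULL
  write_tsv_commented(class_summary,
                      file.path(out_dir, "class_profiles.tsv"), thr_hdr)
  write_tsv_commented(corr_summary,
                      file.path(out_dir, "omics_correlation.tsv"), thr_hdr)

  ## ---- manifest -----------------------------------------------------------
  manifest <- list(
    package = "silacseq",
    version = as.character(utils::packageVersion("silacseq")),
    seed = config$seed, iterations = config$iterations,
    universe_mode = config$universe_mode,
    thresholds = list(protein_fc = config$protein_fc,
                      protein_p = config$protein_p,
                      transcript_fc = config$transcript_fc,
                      transcript_q = config$transcript_q,
                      go_min_log2_cpm = config$go_min_log2_cpm,
                      node_size = config$node_size,
                      elim_cutoff = config$elim_cutoff,
                      go_p = config$go_p),
    synthetic = config$synthetic,
    conditions = conditions, reference = reference)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("[done] %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(proteins = prot, transcripts = trans, go = go_res,
                 overlaps = overlaps, class_profiles = class_summary,
                 omics_correlation = corr_summary, manifest = manifest))
}
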