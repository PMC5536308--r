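## Synthetic-data generators: every pipeline input (proteinGroups-style
## ratio table, count matrix, GO DAG + annotations, gene-class table) with
## known ground truth, so each downstream stage is testable offline.

#' Simulation configuration
#'
#' Collects every knob of the synthetic multi-omics experiment: the study
#' design (conditions, replicates), the true differential-expression
#' structure (per-condition DE fractions or an explicit Venn-region
#' specification), effect sizes and noise levels for the SILAC and count
#' branches, gene-class proportions and the size of the simulated GO DAG.
#'
#' Defaults emulate the study design the pipeline targets: three mutant
#' conditions against a common wild-type reference, three biological
#' replicates, ~10% of genes truly differentially expressed per mutant with
#' a mean absolute log2 fold change of 2, log2 H/L replicate noise of
#' sd 0.2, negative-binomial count dispersion 0.05, and gene classes split
#' 20% oogenic / 10% spermatogenic / 70% gender-neutral.
#'
#' @param n_genes number of genes in the transcriptome.
#' @param n_proteins number of quantified protein groups; the first
#'   `n_proteins` genes double as proteins so that features can be matched
#'   across omics layers.
#' @param conditions character vector of mutant condition labels.
#' @param reference label of the common reference condition.
#' @param replicates_per_condition biological replicates per condition.
#' @param de_fraction per-condition proportion of truly DE genes (recycled).
#' @param overlap_spec optional named numeric vector of target counts for
#'   each Venn region of the per-condition true-DE sets; names are
#'   `&`-joined condition subsets in `conditions` order (see
#'   [region_names()]). When `NULL`, DE sets are drawn independently at
#'   `de_fraction` and the realised region counts are recorded.
#' @param effect_size_log2 mean absolute log2 fold change of true DE genes.
#' @param ratio_noise_sd sd of the log2 H/L replicate noise (SILAC branch).
#' @param nb_dispersion negative-binomial dispersion phi in
#'   `var = mu + phi * mu^2`; 0 gives Poisson counts.
#' @param missing_rate per-cell probability that an H/L ratio is missing.
#' @param class_proportions named proportions for classes
#'   `oogenic`, `spermatogenic`, `neutral`; must sum to 1.
#' @param go_terms number of GO terms per simulated ontology.
#' @param ontologies ontology labels to simulate DAGs for.
#' @param baseline_log2_mean,baseline_log2_sd log2-normal parameters for
#'   per-gene baseline expression.
#' @param lib_size_range range (min, max) from which library sizes are drawn
#'   log-uniformly.
#' @param n_decoys,n_contaminants number of reverse-decoy and contaminant
#'   rows appended to the simulated proteinGroups table.
#' @param seed integer seed; all generators derive their streams from it.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 200, n_proteins = 50, seed = 1)
#' @export
sim_config <- function(n_genes = 2000,
                       n_proteins = 500,
                       conditions = c("fog-1", "cpb-2", "cpb-3"),
                       reference = "wt",
                       replicates_per_condition = 3,
                       de_fraction = 0.1,
                       overlap_spec = NULL,
                       effect_size_log2 = 2,
                       ratio_noise_sd = 0.2,
                       nb_dispersion = 0.05,
                       missing_rate = 0.1,
                       class_proportions = c(oogenic = 0.2,
                                             spermatogenic = 0.1,
                                             neutral = 0.7),
                       go_terms = 50,
                       ontologies = "BP",
                       baseline_log2_mean = 7,
                       baseline_log2_sd = 2,
                       lib_size_range = c(5e5, 2e6),
                       n_decoys = 10,
                       n_contaminants = 5,
                       seed = 1) {
  if (n_genes < 1 || n_proteins < 1) stop_fmt("n_genes and n_proteins must be positive")
  if (n_proteins > n_genes) stop_fmt("n_proteins must not exceed n_genes")
  if (replicates_per_condition < 1) stop_fmt("replicates_per_condition must be positive")
  if (reference %in% conditions) stop_fmt("reference label must not appear in conditions")
  de_fraction <- rep_len(de_fraction, length(conditions))
  names(de_fraction) <- conditions
  if (any(de_fraction < 0 | de_fraction > 1)) stop_fmt("de_fraction must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1) stop_fmt("missing_rate must lie in [0, 1]")
  if (nb_dispersion < 0) stop_fmt("nb_dispersion must be non-negative")
  if (effect_size_log2 < 0) stop_fmt("effect_size_log2 must be non-negative")
  if (ratio_noise_sd < 0) stop_fmt("ratio_noise_sd must be non-negative")
  req <- c("oogenic", "spermatogenic", "neutral")
  if (!all(req %in% names(class_proportions)))
    stop_fmt("class_proportions must be named oogenic/spermatogenic/neutral")
  class_proportions <- class_proportions[req]
  if (abs(sum(class_proportions) - 1) > 1e-12)
    stop_fmt("class_proportions must sum to 1 (got %.15f)", sum(class_proportions))
  if (go_terms < 1) stop_fmt("go_terms must be positive")
  if (!is.null(overlap_spec)) {
    overlap_spec <- validate_overlap_spec(overlap_spec, conditions,
                                          de_fraction, n_genes)
  }
  structure(list(
    n_genes = as.integer(n_genes), n_proteins = as.integer(n_proteins),
    conditions = conditions, reference = reference,
    replicates_per_condition = as.integer(replicates_per_condition),
    de_fraction = de_fraction, overlap_spec = overlap_spec,
    effect_size_log2 = effect_size_log2, ratio_noise_sd = ratio_noise_sd,
    nb_dispersion = nb_dispersion, missing_rate = missing_rate,
    class_proportions = class_proportions, go_terms = as.integer(go_terms),
    ontologies = ontologies,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    lib_size_range = lib_size_range,
    n_decoys = as.integer(n_decoys),
    n_contaminants = as.integer(n_contaminants),
    seed = as.integer(seed)), class = "sim_config")
}

#' Venn region names for a set of condition labels
#'
#' All `2^k - 1` non-empty subsets of `conditions`, each labelled by the
#' member conditions joined with `&` in `conditions` order. Region order is
#' by subset bit pattern (condition i contributes bit `2^(i-1)`).
#'
#' @param conditions character vector of set labels.
#' @return character vector of region names.
#' @export
region_names <- function(conditions) {
  k <- length(conditions)
  vapply(seq_len(2^k - 1L), function(code) {
    paste(conditions[bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) > 0L],
          collapse = "&")
  }, character(1))
}

validate_overlap_spec <- function(spec, conditions, de_fraction, n_genes) {
  rn <- region_names(conditions)
  if (is.null(names(spec)) || !all(names(spec) %in% rn))
    stop_fmt("overlap_spec names must be Venn regions of the conditions: %s",
             paste(setdiff(names(spec), rn), collapse = ", "))
  full <- stats::setNames(numeric(length(rn)), rn)
  full[names(spec)] <- spec
  if (any(full < 0)) stop_fmt("overlap_spec counts must be non-negative")
  if (any(full != round(full))) stop_fmt("overlap_spec counts must be integers")
  if (sum(full) > n_genes)
    stop_fmt("overlap_spec regions sum to %d > n_genes = %d", sum(full), n_genes)
  for (i in seq_along(conditions)) {
    marg <- sum(full[grepl_region(rn, conditions, i)])
    cap <- de_fraction[i] * n_genes
    if (marg > cap + 1e-9)
      stop_fmt("overlap_spec marginal for condition '%s' is %d, exceeding de_fraction * n_genes = %g",
               conditions[i], as.integer(marg), cap)
  }
  full
}

## logical index of regions containing condition i
grepl_region <- function(rn, conditions, i) {
  codes <- seq_along(rn)
  bitwAnd(codes, bitwShiftL(1L, i - 1L)) > 0L
}

#' Generate per-condition true-DE indicator vectors with exact Venn structure
#'
#' When `cfg$overlap_spec` is supplied, genes are assigned to Venn regions so
#' that the region counts of the returned indicator vectors match the
#' specification exactly (not merely in expectation). Otherwise each
#' condition's DE set is an independent uniform draw of
#' `round(de_fraction * n_genes)` genes.
#'
#' @param cfg a [sim_config()].
#' @return logical matrix `n_genes x length(conditions)` with condition
#'   column names; attribute `"regions"` holds the realised region counts.
#' @export
gen_overlap_flags <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, 1L))
  k <- length(cfg$conditions)
  flags <- matrix(FALSE, cfg$n_genes, k,
                  dimnames = list(gene_ids(cfg$n_genes), cfg$conditions))
  rn <- region_names(cfg$conditions)
  if (is.null(cfg$overlap_spec)) {
    for (j in seq_len(k)) {
      nde <- round(cfg$de_fraction[j] * cfg$n_genes)
      flags[sample.int(cfg$n_genes, nde), j] <- TRUE
    }
  } else {
    spec <- cfg$overlap_spec
    pool <- sample.int(cfg$n_genes)        # random gene order, then block-assign
    pos <- 1L
    for (code in seq_along(rn)) {
      cnt <- as.integer(spec[[code]])
      if (cnt == 0L) next
      idx <- pool[pos:(pos + cnt - 1L)]
      pos <- pos + cnt
      members <- bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) > 0L
      flags[idx, members] <- TRUE
    }
  }
  counts <- venn_region_counts_matrix(flags)
  attr(flags, "regions") <- counts
  flags
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

## Venn-region counts straight from a logical membership matrix
venn_region_counts_matrix <- function(flags) {
  k <- ncol(flags)
  code <- as.integer(flags %*% bitwShiftL(1L, seq_len(k) - 1L))
  stats::setNames(tabulate(code, nbins = 2^k - 1L),
                  region_names(colnames(flags)))
}

#' Generate the full simulation ground truth
#'
#' Combines the DE indicators from [gen_overlap_flags()] with signed fold
#' changes (half up-, half down-regulated; magnitude `effect_size_log2`),
#' gene-class labels and GO-term assignments.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_truth` with elements `true_de` (logical
#'   matrix), `true_log2fc` (numeric matrix, genes x conditions),
#'   `class_label` (factor per gene) and `annotations` (see
#'   [gen_annotations()]).
#' @export
gen_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  flags <- gen_overlap_flags(cfg)
  set.seed(child_seed(cfg$seed, 2L))
  fc <- matrix(0, cfg$n_genes, length(cfg$conditions),
               dimnames = dimnames(flags))
  for (j in seq_along(cfg$conditions)) {
    idx <- which(flags[, j])
    if (length(idx)) {
      sign <- rep_len(c(1, -1), length(idx))[sample.int(length(idx))]
      fc[idx, j] <- sign * cfg$effect_size_log2
    }
  }
  ann <- gen_annotations(cfg)
  structure(list(true_de = flags, true_log2fc = fc,
                 class_label = ann$classes$class,
                 annotations = ann,
                 regions = attr(flags, "regions")),
            class = "sim_truth")
}

#' Simulate a MaxQuant-style proteinGroups ratio table
#'
#' Emulates a spike-in SILAC design: a single heavy-labelled reference is
#' mixed into every light sample, so the normalised H/L ratio of protein i
#' in condition c, replicate r is `2^(-true_log2fc[c, i] + eps)` with
#' `eps ~ N(0, ratio_noise_sd^2)` (wild-type has true log2 fold change 0).
#' Each ratio cell is independently missing with probability
#' `missing_rate`. Decoy ("Reverse") and contaminant rows with random
#' ratios are appended, and summed H/L intensities are simulated for the
#' incorporation-efficiency QC.
#'
#' @param cfg a [sim_config()].
#' @param truth a [gen_truth()] result.
#' @return a `data.frame` in the MaxQuant `proteinGroups.txt` dialect with
#'   columns `Protein IDs`, one `Ratio H/L normalized <condition>_<rep>`
#'   column per sample, `Intensity H`, `Intensity L`, `Reverse` and
#'   `Potential contaminant` (flag columns use `"+"`).
#' @export
gen_silac_table <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(child_seed(cfg$seed, 3L))
  np <- cfg$n_proteins
  conds <- c(cfg$reference, cfg$conditions)
  reps <- cfg$replicates_per_condition
  ids <- rownames(truth$true_log2fc)[seq_len(np)]
  cols <- list(`Protein IDs` = ids)
  for (cond in conds) {
    fc <- if (cond == cfg$reference) rep(0, np) else truth$true_log2fc[seq_len(np), cond]
    for (r in seq_len(reps)) {
      ratio <- 2^(-fc + stats::rnorm(np, 0, cfg$ratio_noise_sd))
      if (cfg$missing_rate > 0)
        ratio[stats::runif(np) < cfg$missing_rate] <- NA_real_
      cols[[sprintf("Ratio H/L normalized %s_%d", cond, r)]] <- ratio
    }
  }
  tbl <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  # heavy reference dominates: high incorporation efficiency by construction
  tot <- 2^stats::rnorm(np, 20, 1.5)
  eff <- stats::rbeta(np, 90, 4)
  tbl$`Intensity H` <- tot * eff
  tbl$`Intensity L` <- tot * (1 - eff)
  tbl$Reverse <- ""
  tbl$`Potential contaminant` <- ""
  extra <- cfg$n_decoys + cfg$n_contaminants
  if (extra > 0) {
    junk <- tbl[rep_len(seq_len(np), extra), , drop = FALSE]
    junk$`Protein IDs` <- c(sprintf("REV__d%03d", seq_len(cfg$n_decoys)),
                            sprintf("CON__c%03d", seq_len(cfg$n_contaminants)))
    ratio_cols <- grep("^Ratio H/L normalized ", names(junk))
    for (jc in ratio_cols) junk[[jc]] <- 2^stats::rnorm(extra, 0, 1)
    junk$Reverse <- rep(c("+", ""), c(cfg$n_decoys, cfg$n_contaminants))
    junk$`Potential contaminant` <- rep(c("", "+"), c(cfg$n_decoys, cfg$n_contaminants))
    tbl <- rbind(tbl, junk)
    rownames(tbl) <- NULL
  }
  tbl
}

#' Simulate a negative-binomial count matrix with sample metadata
#'
#' Counts follow `NB(mean = pi_i * 2^true_log2fc[c, i] * L_s,
#' dispersion = phi)` where `pi_i` are normalised log-normal baseline
#' abundances, `L_s` library sizes drawn log-uniformly from
#' `cfg$lib_size_range`, and `phi = cfg$nb_dispersion` (0 gives Poisson).
#'
#' @param cfg a [sim_config()].
#' @param truth a [gen_truth()] result.
#' @return list with `counts` (integer matrix genes x samples), `samples`
#'   (data.frame: sample, condition, stage, replicate, run) and
#'   `lib_sizes` (the drawn target library sizes).
#' @export
gen_counts <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(child_seed(cfg$seed, 4L))
  conds <- c(cfg$reference, cfg$conditions)
  reps <- cfg$replicates_per_condition
  samples <- expand.grid(replicate = seq_len(reps), condition = conds,
                         stringsAsFactors = FALSE)[, 2:1]
  samples$sample <- sprintf("%s_%d", samples$condition, samples$replicate)
  samples$stage <- "YA"
  samples$run <- "run1"
  samples <- samples[, c("sample", "condition", "stage", "replicate", "run")]
  base <- 2^stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  pi <- base / sum(base)
  lo <- log(cfg$lib_size_range[1]); hi <- log(cfg$lib_size_range[2])
  lib <- exp(stats::runif(nrow(samples), lo, hi))
  counts <- matrix(0L, cfg$n_genes, nrow(samples),
                   dimnames = list(rownames(truth$true_log2fc), samples$sample))
  for (s in seq_len(nrow(samples))) {
    cond <- samples$condition[s]
    fc <- if (cond == cfg$reference) 0 else truth$true_log2fc[, cond]
    mu <- pi * 2^fc * lib[s]
    counts[, s] <- if (cfg$nb_dispersion == 0) {
      stats::rpois(cfg$n_genes, mu)
    } else {
      stats::rnbinom(cfg$n_genes, size = 1 / cfg$nb_dispersion, mu = mu)
    }
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, samples = samples, lib_sizes = lib)
}

#' Simulate a GO DAG, gene annotations and gene-class labels
#'
#' Each simulated ontology is a rooted acyclic term graph: the first term is
#' the root and every later term attaches to one or two previously created
#' terms, so every term reaches the root. Genes receive one to three direct
#' term annotations with evidence codes drawn from a realistic mix
#' (including the excluded codes ND/IEA/NR); the true-path rule holds after
#' [propagate_annotations()]. Class labels are drawn at
#' `cfg$class_proportions`.
#'
#' @param cfg a [sim_config()].
#' @return list with `dag` (data.frame: child, parent, ontology), `terms`
#'   (data.frame: term, ontology), `annotations` (data.frame: gene, term,
#'   evidence_code) and `classes` (data.frame: gene, class).
#' @export
gen_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, 5L))
  genes <- gene_ids(cfg$n_genes)
  edges <- list(); terms <- list()
  for (ont in cfg$ontologies) {
    tid <- sprintf("GO:%s%04d", ont, seq_len(cfg$go_terms))
    terms[[ont]] <- data.frame(term = tid, ontology = ont,
                               stringsAsFactors = FALSE)
    if (cfg$go_terms > 1L) {
      for (i in 2:cfg$go_terms) {
        npar <- if (i > 3) sample(1:2, 1) else 1L
        par <- sample(seq_len(i - 1L), min(npar, i - 1L))
        edges[[length(edges) + 1L]] <-
          data.frame(child = tid[i], parent = tid[par], ontology = ont,
                     stringsAsFactors = FALSE)
      }
    }
  }
  dag <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(),
               ontology = character(), stringsAsFactors = FALSE)
  terms <- do.call(rbind, terms)
  rownames(terms) <- NULL
  ev_codes <- c("EXP", "IDA", "IMP", "IGI", "ISS", "IEA", "ND", "NR")
  ev_prob  <- c(0.15, 0.2, 0.15, 0.1, 0.15, 0.15, 0.05, 0.05)
  ann <- lapply(cfg$ontologies, function(ont) {
    tid <- terms$term[terms$ontology == ont]
    n_ann <- sample(1:min(3L, length(tid)), cfg$n_genes, replace = TRUE)
    g <- rep(genes, n_ann)
    data.frame(gene = g,
               term = unlist(lapply(n_ann, function(k) sample(tid, k))),
               evidence_code = sample(ev_codes, length(g), replace = TRUE,
                                      prob = ev_prob),
               stringsAsFactors = FALSE)
  })
  ann <- unique(do.call(rbind, ann))
  rownames(ann) <- NULL
  classes <- data.frame(
    gene = genes,
    class = sample(names(cfg$class_proportions), cfg$n_genes, replace = TRUE,
                   prob = cfg$class_proportions),
    stringsAsFactors = FALSE)
  list(dag = dag, terms = terms, annotations = ann, classes = classes)
}

#' Simulate all pipeline inputs at once
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_data` with `config`, `truth`,
#'   `protein_groups` (MaxQuant-style data.frame), `counts`, `samples`,
#'   `lib_sizes` and the annotation tables from [gen_annotations()].
#' @export
simulate_experiment <- function(cfg) {
  truth <- gen_truth(cfg)
  pg <- gen_silac_table(cfg, truth)
  cm <- gen_counts(cfg, truth)
  structure(list(config = cfg, truth = truth, protein_groups = pg,
                 counts = cm$counts, samples = cm$samples,
                 lib_sizes = cm$lib_sizes,
                 dag = truth$annotations$dag,
                 terms = truth$annotations$terms,
                 annotations = truth$annotations$annotations,
                 classes = truth$annotations$classes),
            class = "sim_data")
}

#' Write simulated inputs to disk as plain-text files
#'
#' Writes the proteinGroups-style TSV, counts TSV, sample metadata TSV, DAG
#' edge list, annotation TSV, class TSV, per-condition truth TSV and the
#' configuration as YAML.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    protein_groups = file.path(dir, "proteinGroups.txt"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    dag = file.path(dir, "go_dag.tsv"),
    annotations = file.path(dir, "go_annotations.tsv"),
    classes = file.path(dir, "gene_classes.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "sim_config.yaml"))
  utils::write.table(sim$protein_groups, paths["protein_groups"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NaN")
  cm <- data.frame(gene = rownames(sim$counts), sim$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cm, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$samples, paths["samples"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$dag, paths["dag"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$annotations, paths["annotations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$classes, paths["classes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- data.frame(gene = rownames(sim$truth$true_log2fc),
                   sim$truth$true_log2fc, check.names = FALSE)
  utils::write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- sim$config
  cfg_list <- unclass(cfg)
  cfg_list$de_fraction <- as.list(cfg$de_fraction)
  cfg_list$class_proportions <- as.list(cfg$class_proportions)
  if (!is.null(cfg$overlap_spec)) cfg_list$overlap_spec <- as.list(cfg$overlap_spec)
  yaml::write_yaml(cfg_list, paths["config"])
  invisible(paths)
}

#' Split a count matrix into simulated technical sequencing runs
#'
#' Binomially thins each library into `n_runs` technical runs whose sum
#' equals the original counts exactly; useful for exercising
#' [sum_technical_runs()].
#'
#' @param counts integer matrix genes x samples.
#' @param n_runs number of runs per library.
#' @param seed integer seed.
#' @return list of `n_runs` count matrices with identical dimnames.
#' @export
split_runs <- function(counts, n_runs = 2, seed = 1) {
  set.seed(as.integer(seed))
  remaining <- counts
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs - 1L)) {
    drawn <- matrix(stats::rbinom(length(remaining), remaining,
                                  1 / (n_runs - r + 1)),
                    nrow(remaining), dimnames = dimnames(counts))
    out[[r]] <- drawn
    remaining <- remaining - drawn
  }
  out[[n_runs]] <- remaining
  out
}
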