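test_that("gen_overlap_flags reproduces an overlap specification exactly", {
  cfg <- sim_config(n_genes = 100, n_proteins = 10, conditions = c("A", "B", "C"),
                    de_fraction = 1,
                    overlap_spec = c(`A&B&C` = 5), seed = 3)
  flags <- gen_overlap_flags(cfg)
  expect_equal(sum(flags[, "A"] & flags[, "B"] & flags[, "C"]), 5)
  expect_equal(unname(colSums(flags)), c(5, 5, 5))

  cfg0 <- sim_config(n_genes = 100, n_proteins = 10, conditions = c("A", "B", "C"),
                     overlap_spec = stats::setNames(numeric(0), character(0)),
                     seed = 3)
  expect_true(!any(gen_overlap_flags(cfg0)))

  cfg2 <- sim_config(n_genes = 10, n_proteins = 5, conditions = c("A", "B"), de_fraction = 1,
                     overlap_spec = c(A = 2, B = 3, `A&B` = 1), seed = 3)
  fl <- gen_overlap_flags(cfg2)
  expect_equal(sum(fl[, "A"]), 3)
  expect_equal(sum(fl[, "B"]), 4)
  expect_equal(sum(fl[, "A"] & fl[, "B"]), 1)
  expect_equal(attr(fl, "regions"),
               c(A = 2L, B = 3L, `A&B` = 1L))
})

test_that("infeasible overlap specifications are rejected, naming the marginal", {
  expect_error(
    sim_config(n_genes = 100, n_proteins = 10, conditions = c("A", "B"), de_fraction = 0.02,
               overlap_spec = c(A = 5)),
    "marginal for condition 'A'")
  expect_error(
    sim_config(n_genes = 10, n_proteins = 5, conditions = c("A", "B"), de_fraction = 1,
               overlap_spec = c(A = 8, B = 8)),
    "n_genes")
  expect_error(
    sim_config(n_genes = 10, n_proteins = 5, conditions = c("A", "B"),
               overlap_spec = c(bogus = 1)),
    "bogus")
})

test_that("identical config yields identical outputs; configs validate", {
  cfg <- small_cfg(seed = 5)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(small_cfg(seed = 5))
  expect_identical(s1, s2)
  expect_error(sim_config(class_proportions = c(oogenic = 0.5,
                                                spermatogenic = 0.5,
                                                neutral = 0.1)),
               "sum to 1")
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
})

test_that("noise-free SILAC data recovers true fold changes to machine precision", {
  cfg <- small_cfg(ratio_noise_sd = 0, missing_rate = 0, de_fraction = 0.1)
  truth <- gen_truth(cfg)
  pg <- gen_silac_table(cfg, truth)
  path <- write_pg_fixture(pg)
  rt <- read_protein_groups(path)
  for (mut in cfg$conditions) {
    res <- silac_de(rt, mutant = mut)
    truefc <- truth$true_log2fc[res$protein_group_id, mut]
    expect_equal(res$log2fc_mean, unname(truefc), tolerance = 1e-12)
  }
})

test_that("fully missing ratios leave no quantifiable protein downstream", {
  cfg <- small_cfg(missing_rate = 1)
  pg <- gen_silac_table(cfg, gen_truth(cfg))
  ratios <- as.matrix(pg[, grep("^Ratio", names(pg))])
  expect_true(all(is.na(ratios[seq_len(cfg$n_proteins), ])))
  rt <- read_protein_groups(write_pg_fixture(pg))
  wt_cols <- grep("^wt_", rt$experiments, value = TRUE)
  mut_cols <- grep("^mutA_", rt$experiments, value = TRUE)
  d <- deconvolute(rt$ratio[seq_len(cfg$n_proteins), wt_cols],
                   rt$ratio[seq_len(cfg$n_proteins), mut_cols])
  expect_equal(nrow(d), 0L)
})

test_that("count generator hits its stated moments", {
  # Poisson limit: dispersion 0 gives variance/mean ~ 1 across genes
  cfg <- small_cfg(n_genes = 2000, nb_dispersion = 0, de_fraction = 0,
                   conditions = "mutA", lib_size_range = c(1e6, 1e6))
  cm <- gen_counts(cfg, gen_truth(cfg))
  m <- rowMeans(cm$counts); v <- apply(cm$counts, 1, var)
  keep <- m > 20
  expect_equal(mean(v[keep] / m[keep]), 1, tolerance = 0.1)

  # null: per-gene two-group mean log2 CPM ratio centred on 0
  cp <- cpm(cm$counts)
  lfc <- log2(rowMeans(cp[keep, cm$samples$condition == "mutA"]) /
              rowMeans(cp[keep, cm$samples$condition == "wt"]))
  expect_lt(abs(mean(lfc)), 0.02)
})

test_that("a 4-fold effect lands in the [3, 5] empirical ratio band", {
  # scaled-down Monte-Carlo over 25 seeds (spec's full check uses >= 1000)
  ratios <- vapply(1:25, function(s) {
    cfg <- sim_config(n_genes = 50, n_proteins = 10, conditions = "mutA",
                      de_fraction = 0.02, overlap_spec = c(mutA = 1),
                      effect_size_log2 = 2,
                      nb_dispersion = 0.01, baseline_log2_mean = 10,
                      baseline_log2_sd = 0.1,
                      lib_size_range = c(1e6, 1e6), seed = s)
    truth <- gen_truth(cfg)
    up <- which(truth$true_log2fc[, 1] == 2)[1]
    cm <- gen_counts(cfg, truth)
    cp <- cpm(cm$counts)
    mean(cp[up, cm$samples$condition == "mutA"]) /
      mean(cp[up, cm$samples$condition == "wt"])
  }, numeric(1))
  expect_true(all(ratios >= 3 & ratios <= 5))
})

test_that("annotation generator builds a rooted DAG, valid classes", {
  cfg <- small_cfg(n_genes = 1000, go_terms = 30)
  ann <- gen_annotations(cfg)
  dag <- go_dag(ann$dag)                 # errors on cycles
  expect_length(dag$roots, length(cfg$ontologies))
  anc <- go_ancestors(dag)
  non_roots <- setdiff(dag$terms, dag$roots)
  expect_true(all(vapply(non_roots,
                         function(t) any(dag$roots %in% anc[[t]]),
                         logical(1))))

  # single-term ontology: one root, annotated to every gene
  cfg1 <- small_cfg(go_terms = 1)
  a1 <- gen_annotations(cfg1)
  expect_equal(nrow(a1$dag), 0L)
  expect_setequal(unique(a1$annotations$gene), gene_ids(cfg1$n_genes))
  expect_equal(unique(a1$annotations$term), a1$terms$term)

  # degenerate class proportions
  cfg2 <- small_cfg(class_proportions = c(oogenic = 0, spermatogenic = 0,
                                          neutral = 1))
  expect_true(all(gen_annotations(cfg2)$classes$class == "neutral"))

  # label counts within 99% binomial bounds of (200, 100, 700)
  cfg3 <- small_cfg(n_genes = 1000,
                    class_proportions = c(oogenic = 0.2, spermatogenic = 0.1,
                                          neutral = 0.7))
  counts <- table(gen_annotations(cfg3)$classes$class)
  for (cl in names(cfg3$class_proportions)) {
    p <- cfg3$class_proportions[[cl]]
    expect_gte(counts[[cl]], qbinom(0.005, 1000, p))
    expect_lte(counts[[cl]], qbinom(0.995, 1000, p))
  }
})

test_that("written inputs round-trip through the file readers", {
  cfg <- small_cfg(n_genes = 120, n_proteins = 40, go_terms = 10)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_inputs(sim, dir)
  expect_true(all(file.exists(paths)))
  rt <- read_protein_groups(paths[["protein_groups"]])
  expect_length(rt$id, cfg$n_proteins)   # decoys/contaminants removed
  cm <- read_tsv_plain(paths[["counts"]])
  expect_identical(cm$gene, rownames(sim$counts))
  expect_equal(as.matrix(cm[, -1]), sim$counts, ignore_attr = TRUE)
  y <- yaml::read_yaml(paths[["config"]])
  expect_equal(y$seed, cfg$seed)
})

test_that("split_runs partitions counts exactly", {
  cfg <- small_cfg(n_genes = 50)
  cm <- gen_counts(cfg, gen_truth(cfg))
  runs <- split_runs(cm$counts, n_runs = 3, seed = 9)
  expect_identical(sum_technical_runs(runs), cm$counts)
})
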