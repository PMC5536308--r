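test_that("go_dag validates structure and computes longest-path depths", {
  dag <- diamond_dag()
  expect_setequal(dag$roots, "a")
  expect_equal(unname(dag$depth[c("a", "b", "c", "d")]), c(0, 1, 1, 2))
  expect_error(go_dag(data.frame(child = c("x", "y"), parent = c("y", "x"))),
               "cycle")
  anc <- go_ancestors(dag)
  expect_setequal(anc[["d"]], c("a", "b", "c"))
  expect_length(anc[["a"]], 0)
})

test_that("evidence-code filtering drops only the excluded triples", {
  ann <- data.frame(gene = c("g1", "g2", "g3"),
                    term = c("t1", "t1", "t2"),
                    evidence_code = c("EXP", "IEA", "IDA"))
  expect_equal(nrow(filter_evidence(ann)), 2)
  expect_identical(filter_evidence(ann, exclude = character()), ann)
  expect_equal(nrow(filter_evidence(ann, exclude = c("EXP", "IEA", "IDA"))), 0)
})

test_that("propagation closes annotations under ancestors and is idempotent", {
  chain <- go_dag(data.frame(child = c("c", "b"), parent = c("b", "a")))
  ann <- data.frame(gene = "g1", term = "c")
  p1 <- propagate_annotations(chain, ann)
  expect_setequal(p1$term, c("a", "b", "c"))
  p2 <- propagate_annotations(chain, p1)
  srt <- function(x) {
    x <- x[order(x$gene, x$term), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(srt(p2), srt(p1))
  # diamond: gene reaches every term exactly once
  pd <- propagate_annotations(diamond_dag(), data.frame(gene = "g1", term = "d"))
  expect_equal(nrow(pd), 4)
  expect_setequal(pd$term, c("a", "b", "c", "d"))
})

test_that("fisher_two_tailed matches enumeration and fisher.test", {
  expect_equal(fisher_two_tailed(2, 0, 0, 2), 1 / 3)
  expect_equal(fisher_two_tailed(1, 1, 1, 1), 1)
  # transpose invariance
  expect_equal(fisher_two_tailed(3, 1, 2, 7), fisher_two_tailed(3, 2, 1, 7))
  set.seed(42)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_two_tailed(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_two_tailed(-1, 0, 0, 0), "non-negative")
})

## worked elim fixture: parent (20 genes) contains child (10 genes); all 10
## child genes are the interesting set within a 100-gene universe
elim_fixture <- function() {
  genes <- sprintf("u%03d", 1:100)
  dag <- go_dag(data.frame(child = "child", parent = "parent"))
  ann <- rbind(data.frame(gene = genes[1:10], term = "child"),
               data.frame(gene = genes[1:20], term = "parent"))
  list(dag = dag, ann = ann, universe = genes, interesting = genes[1:10])
}

test_that("elim removes a significant child's genes before testing the parent", {
  fx <- elim_fixture()
  res <- elim_enrichment(fx$dag, fx$ann, fx$universe, fx$interesting,
                         node_size = 10, elim_cutoff = 0.01)
  child <- res[res$term == "child", ]
  parent <- res[res$term == "parent", ]
  expect_lt(child$p_fisher_two_tailed, 1e-6)
  expect_equal(child$significant_annotated, 10)
  expect_equal(child$direction, "enriched")
  # parent retested on its 10 remaining genes with 0 interesting left
  expect_equal(parent$annotated_in_universe, 10)
  expect_equal(parent$significant_annotated, 0)
  expect_equal(parent$p_fisher_two_tailed, 1)
})

test_that("elim_cutoff = 0 reduces to the classic per-term Fisher test", {
  cfg <- small_cfg(go_terms = 15, n_genes = 200)
  ann <- gen_annotations(cfg)
  dag <- go_dag(ann$dag)
  prop <- propagate_annotations(dag, filter_evidence(ann$annotations))
  universe <- gene_ids(cfg$n_genes)
  set.seed(8)
  interesting <- sample(universe, 40)
  res <- elim_enrichment(dag, prop, universe, interesting,
                         node_size = 5, elim_cutoff = 0)
  # independent oracle: per-term Fisher via stats::fisher.test
  sets <- split(prop$gene, prop$term)
  for (i in seq_len(nrow(res))) {
    gs <- unique(sets[[res$term[i]]])
    a <- sum(gs %in% interesting)
    tab <- matrix(c(a, length(gs) - a,
                    40 - a, 200 - length(gs) - 40 + a), 2, byrow = TRUE)
    expect_equal(res$p_fisher_two_tailed[i], stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
    expect_equal(res$annotated_in_universe[i], length(gs))
  }
})

test_that("node_size filters terms and raising it never adds terms", {
  fx <- elim_fixture()
  res9 <- elim_enrichment(fx$dag, fx$ann, fx$universe, fx$interesting,
                          node_size = 11)
  expect_false("child" %in% res9$term)      # 10 < 11: excluded entirely
  sizes <- c(1, 5, 10, 15, 25)
  terms_at <- lapply(sizes, function(ns)
    elim_enrichment(fx$dag, fx$ann, fx$universe, fx$interesting,
                    node_size = ns)$term)
  for (i in seq_along(sizes)[-1])
    expect_true(all(terms_at[[i]] %in% terms_at[[i - 1]]))
})

test_that("elim decorrelates a single enriched leaf from its ancestors", {
  # chain root <- mid <- leaf; leaf genes are the enriched set
  genes <- sprintf("g%03d", 1:200)
  dag <- go_dag(data.frame(child = c("leaf", "mid"), parent = c("mid", "root")))
  ann <- rbind(data.frame(gene = genes[1:15], term = "leaf"),
               data.frame(gene = genes[1:60], term = "mid"),
               data.frame(gene = genes, term = "root"))
  interesting <- genes[1:15]
  res <- elim_enrichment(dag, ann, genes, interesting, node_size = 10,
                         elim_cutoff = 0.01)
  expect_lt(res$p_fisher_two_tailed[res$term == "leaf"], 0.01)
  expect_gt(res$p_fisher_two_tailed[res$term == "mid"], 0.05)
  expect_gt(res$p_fisher_two_tailed[res$term == "root"], 0.05)
  # without elim the ancestors inherit the signal
  res0 <- elim_enrichment(dag, ann, genes, interesting, node_size = 10,
                          elim_cutoff = 0)
  expect_lt(res0$p_fisher_two_tailed[res0$term == "mid"], 0.01)
})

test_that("interesting genes must belong to the universe", {
  fx <- elim_fixture()
  expect_error(elim_enrichment(fx$dag, fx$ann, fx$universe[1:50], fx$universe[60]),
               "not in the universe")
})
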