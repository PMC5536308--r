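test_that("technical runs are summed per (gene, library)", {
  m1 <- matrix(3L, 1, 1, dimnames = list("g1", "lib1"))
  m2 <- matrix(4L, 1, 1, dimnames = list("g1", "lib1"))
  expect_equal(sum_technical_runs(list(m1, m2)),
               matrix(7L, 1, 1, dimnames = list("g1", "lib1")))
  expect_identical(sum_technical_runs(list(m1)), m1)
  m3 <- matrix(1L, 1, 1, dimnames = list("g2", "lib1"))
  expect_error(sum_technical_runs(list(m1, m3)), "gene universe")
})

test_that("TMM factors behave on degenerate inputs and match edgeR", {
  set.seed(10)
  y <- matrix(rnbinom(200, mu = 50, size = 5) + 1L, 100, 2)
  same <- cbind(y[, 1], y[, 1])
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  doubled <- cbind(y[, 1], 2L * y[, 1])
  expect_equal(unname(tmm_factors(doubled)), c(1, 1))   # pure depth absorbed
  zero <- cbind(y[, 1], 0L)
  expect_error(tmm_factors(zero), "all-zero")

  skip_if_not_installed("edgeR")
  for (s in 1:4) {
    set.seed(s)
    n <- 4 + s %% 3
    yy <- matrix(rnbinom(300 * n, mu = exp(runif(300, 2, 9)), size = 3) + 1L,
                 300, n)
    f_pkg <- unname(tmm_factors(yy))
    f_ref <- edgeR::calcNormFactors(edgeR::DGEList(yy))$samples$norm.factors
    expect_equal(f_pkg, f_ref, tolerance = 1e-10)
    expect_equal(exp(mean(log(f_pkg))), 1, tolerance = 1e-12)
  }
})

test_that("CPM is a per-million rescaling with finite log output", {
  y <- matrix(c(10L, 990L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(cpm(y)[, 1]), c(10000, 990000))
  y0 <- matrix(c(0L, 1000L), 2, 1)
  expect_true(all(is.finite(cpm(y0, log = TRUE))))
  # doubling counts and library size leaves CPM unchanged
  expect_equal(cpm(y), cpm(2L * y))
  expect_error(cpm(y, factors = 0), "positive")
})

test_that("common dispersion is calibrated on Poisson and NB counts", {
  # Poisson: phi ~ 0
  for (s in 1:3) {
    cfg <- sim_config(n_genes = 2000, n_proteins = 10, conditions = "mutA",
                      de_fraction = 0, nb_dispersion = 0, seed = 300 + s)
    cm <- gen_counts(cfg, gen_truth(cfg))
    expect_lt(abs(estimate_common_dispersion(cm$counts, cm$samples$condition)),
              0.02)
  }
  # NB phi = 0.1: within +-30%
  for (s in 1:3) {
    cfg <- sim_config(n_genes = 2000, n_proteins = 10, conditions = "mutA",
                      de_fraction = 0, nb_dispersion = 0.1, seed = 400 + s)
    cm <- gen_counts(cfg, gen_truth(cfg))
    phi <- estimate_common_dispersion(cm$counts, cm$samples$condition)
    expect_gt(phi, 0.07); expect_lt(phi, 0.13)
  }
  # single replicate per group: inestimable
  y <- matrix(rpois(20, 50), 10, 2)
  expect_error(estimate_common_dispersion(y, c("a", "b")), "two samples")
})

test_that("the NB exact test honours both tail conventions and symmetry", {
  expect_equal(nb_exact_test(10, 0, phi = 0, two_sided = "doubled"),
               2 / 1024)
  expect_equal(nb_exact_test(10, 0, phi = 0, two_sided = "minlik"),
               2 / 1024)  # only x = 0 and x = 10 are as improbable
  expect_equal(nb_exact_test(7, 7, phi = 0.1), 1)     # A = B
  expect_equal(nb_exact_test(0, 0, phi = 0.1), 1)
  for (phi in c(0, 0.05, 0.4)) {
    p_ab <- nb_exact_test(c(5, 9), c(21, 30), phi)
    p_ba <- nb_exact_test(c(21, 30), c(5, 9), phi)
    expect_equal(p_ab, p_ba)
    expect_gt(p_ab, 0); expect_lte(p_ab, 1)
  }
  # dispersion widens the null: p increases with phi
  p0 <- nb_exact_test(40, 10, phi = 0)
  p1 <- nb_exact_test(40, 10, phi = 0.5)
  expect_gt(p1, p0)
  # library-size equalisation: counts proportional to depth carry no signal
  expect_equal(nb_exact_test(20, 10, phi = 0, lib_a = 2, lib_b = 1), 1)
  expect_lt(nb_exact_test(20, 20, phi = 0, lib_a = 4, lib_b = 1), 0.1)
  expect_error(nb_exact_test(1, 1, phi = -1), "non-negative")
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  # brute-force definition on random short inputs
  brute <- function(p) {
    m <- length(p)
    r <- rank(p, ties.method = "first")
    vapply(seq_along(p), function(i) {
      min(1, min((p * m / r)[p >= p[i]]))
    }, numeric(1))
  }
  set.seed(77)
  for (rep in 1:20) {
    p <- round(runif(sample(1:8, 1)), 3)
    expect_equal(bh_adjust(p), brute(p))
  }
  # permutation equivariance
  p <- runif(10)
  perm <- sample(10)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold change and SEM come from replicate-paired CPM ratios", {
  r <- fc_sem_from_replicates(c(100, 100, 100), c(200, 200, 200))
  expect_equal(unname(r$log2fc_mean), 1); expect_equal(unname(r$log2fc_sem), 0)
  r0 <- fc_sem_from_replicates(c(3, 7, 11), c(3, 7, 11))
  expect_equal(unname(r0$log2fc_mean), 0); expect_equal(unname(r0$log2fc_sem), 0)
  r2 <- fc_sem_from_replicates(c(1, 1, 1), c(2, 4, 8))
  expect_equal(unname(r2$log2fc_mean), 2)
  expect_equal(unname(r2$log2fc_sem), 1 / sqrt(3))
})

test_that("transcript DE calls apply strict thresholds and the GO filter", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    log2fc_mean = c(1, 1, 1),
                    bh_adjusted_p = c(0.005, 0.005, 0.01),
                    mean_log2_cpm = c(9, 7, 9))
  out <- call_de_transcripts(res, min_log2_cpm = 8)
  expect_equal(out$is_de, c(TRUE, TRUE, FALSE))    # q = 0.01 exactly: not DE
  expect_equal(out$go_eligible, c(TRUE, FALSE, FALSE))
  out2 <- call_de_transcripts(res)
  expect_null(out2$go_eligible)
})

test_that("rnaseq_de recovers simulated differential expression", {
  cfg <- sim_config(n_genes = 800, n_proteins = 10, conditions = "mutA",
                    de_fraction = 0.1, effect_size_log2 = 2,
                    nb_dispersion = 0.05, seed = 31)
  truth <- gen_truth(cfg)
  cm <- gen_counts(cfg, truth)
  res <- rnaseq_de(cm$counts, cm$samples, "mutA")
  expect_equal(nrow(res), cfg$n_genes)
  expect_true(all(res$bh_adjusted_p >= res$p_value))
  truede <- rownames(truth$true_de)[truth$true_de[, 1]]
  called <- res$gene_id[res$is_de]
  expect_gt(mean(truede %in% called), 0.8)      # sensitivity
  fc_hat <- res$log2fc_mean[match(truede, res$gene_id)]
  expect_equal(sign(fc_hat), unname(sign(truth$true_log2fc[truede, 1])))
})
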