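## Count-based transcriptome differential expression: technical-run
## summing, TMM normalisation, CPM, method-of-moments common dispersion,
## a conditional negative-binomial exact test, BH adjustment and DE calls.
##
## The NB exact test is a documented substitute for a packaged count-DE
## fit: counts are equalised to a common effective library size, summed
## per group, and the group-A total is tested conditionally on the pooled
## total (beta-binomial split; plain binomial when the dispersion is 0).

#' Sum counts from technical sequencing runs of the same libraries
#'
#' Element-wise integer sum of per-run count tables sharing the same gene
#' universe and library (column) ids.
#'
#' @param run_tables list of integer count matrices (genes x libraries)
#'   with identical dimnames.
#' @return a single summed count matrix.
#' @export
sum_technical_runs <- function(run_tables) {
  if (!length(run_tables)) stop_fmt("no run tables supplied")
  ref <- run_tables[[1]]
  for (i in seq_along(run_tables)) {
    t <- run_tables[[i]]
    if (!identical(rownames(t), rownames(ref)))
      stop_fmt("run table %d has a different gene universe", i)
    if (!identical(colnames(t), colnames(ref)))
      stop_fmt("run table %d has different library ids", i)
  }
  out <- Reduce(`+`, run_tables)
  storage.mode(out) <- "integer"
  out
}

#' TMM normalisation factors
#'
#' Trimmed mean of M-values: for each sample against a reference column,
#' gene-wise log2 ratios (M) and average log2 abundances (A) are computed
#' on library-size-normalised counts; genes in the upper/lower 30% of M and
#' 5% of A are trimmed; the remaining M values are averaged with inverse
#' approximate-variance (precision) weights. Factors are normalised so
#' their geometric mean is 1. The reference sample defaults to the column
#' whose 75th count percentile (as a fraction of library size) is closest
#' to the mean across samples.
#'
#' @param counts integer matrix genes x samples.
#' @param ref_column optional reference column index or name.
#' @param logratio_trim,sum_trim trim fractions for M and A (defaults 0.3
#'   and 0.05).
#' @param do_weighting use precision weights (default `TRUE`).
#' @return numeric vector of per-sample scaling factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, ref_column = NULL, logratio_trim = 0.3,
                        sum_trim = 0.05, do_weighting = TRUE) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_fmt("sample '%s' has all-zero counts",
             colnames(counts)[which(lib == 0)[1]] %||% which(lib == 0)[1])
  if (is.null(ref_column)) {
    q75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
    ref_column <- which.min(abs(q75 - mean(q75)))
  }
  if (is.character(ref_column)) ref_column <- match(ref_column, colnames(counts))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref_column], lib[j], lib[ref_column],
             logratio_trim, sum_trim, do_weighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim,
                     do_weighting) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  ok <- obs > 0 & ref > 0
  if (!any(ok)) return(1)
  m <- log2(p_obs[ok] / p_ref[ok])
  a <- 0.5 * log2(p_obs[ok] * p_ref[ok])
  # delta-method binomial variance of M, as in the original TMM derivation
  w <- (n_obs - obs[ok]) / (n_obs * obs[ok]) + (n_ref - ref[ok]) / (n_ref * ref[ok])
  if (max(abs(m)) < 1e-6) return(1)   # identical profiles
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1;      hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  tm <- if (do_weighting) sum(m[keep] / w[keep]) / sum(1 / w[keep]) else
    mean(m[keep])
  if (!is.finite(tm)) tm <- 0
  2^tm
}

#' Counts per million
#'
#' `count / (library_size * factor) * 1e6`; with `log = TRUE` returns
#' `log2(CPM + prior)`.
#'
#' @param counts integer matrix genes x samples.
#' @param factors per-sample normalisation factors (default all 1).
#' @param log return log2 values.
#' @param prior prior count added on the CPM scale before taking logs
#'   (default 0.5).
#' @param lib_sizes optional library sizes (default `colSums(counts)`).
#' @return numeric matrix genes x samples.
#' @export
cpm <- function(counts, factors = NULL, log = FALSE, prior = 0.5,
                lib_sizes = NULL) {
  counts <- as.matrix(counts)
  lib <- lib_sizes %||% colSums(counts)
  factors <- factors %||% rep(1, ncol(counts))
  if (any(factors <= 0)) stop_fmt("normalisation factors must be positive")
  out <- sweep(counts, 2, lib * factors, "/") * 1e6
  if (log) log2(out + prior) else out
}

#' Method-of-moments common negative-binomial dispersion
#'
#' Counts are rescaled to a common effective library size; within each
#' group with at least two samples, per-gene means and variances are
#' computed, giving a gene-wise moment estimate
#' `phi_g = sum_groups(var - mean * mean(1/c_j)) / sum_groups(mean^2)`
#' (the `1/c_j` term corrects the Poisson part of the variance for the
#' rescaling). The common dispersion is the equal-weight average of
#' `phi_g` over genes whose rescaled mean count is at least `min_count`
#' (so that a handful of very highly expressed genes cannot dominate),
#' falling back to the ratio of pooled sums when fewer than 50 genes
#' qualify; the result is floored at 0.
#'
#' @param counts integer matrix genes x samples.
#' @param groups factor/character of group membership per sample.
#' @param eff_lib optional effective library sizes (library x TMM factor);
#'   defaults to `colSums(counts)`.
#' @param min_count minimum rescaled mean count for a gene to enter the
#'   equal-weight average (default 32).
#' @return non-negative dispersion estimate `phi`.
#' @export
estimate_common_dispersion <- function(counts, groups, eff_lib = NULL,
                                       min_count = 32) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  eff_lib <- eff_lib %||% colSums(counts)
  tab <- table(groups)
  if (!any(tab >= 2))
    stop_fmt("dispersion inestimable: no group has at least two samples")
  geo <- exp(mean(log(eff_lib)))
  scale <- eff_lib / geo
  y <- sweep(counts, 2, scale, "/")
  num <- 0; den <- 0; mu <- 0
  for (g in names(tab)[tab >= 2]) {
    j <- which(groups == g)
    m <- rowMeans(y[, j, drop = FALSE])
    v <- apply(y[, j, drop = FALSE], 1, stats::var)
    num <- num + (v - m * mean(1 / scale[j]))
    den <- den + m^2
    mu <- pmax(mu, m)
  }
  eligible <- mu >= min_count & den > 0
  phi <- if (sum(eligible) >= 50) mean(num[eligible] / den[eligible]) else
    sum(num) / sum(den)
  max(0, phi)
}

#' Conditional negative-binomial exact test for one gene
#'
#' Replicate counts are equalised to the common (geometric-mean) effective
#' library size and summed per group; the group-A total is then tested
#' against the beta-binomial conditional distribution of the pooled total
#' (binomial split when `phi = 0`). Two-sided p-values sum the
#' probabilities of all outcomes no more probable than the observed one
#' (`two_sided = "minlik"`, default) or double the smaller tail
#' (`"doubled"`), capped at 1.
#'
#' @param y_a,y_b numeric vectors of replicate counts in groups A and B.
#' @param phi NB dispersion (>= 0).
#' @param lib_a,lib_b effective library sizes per replicate (default 1s,
#'   i.e. already equalised).
#' @param two_sided tail convention.
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(y_a, y_b, phi, lib_a = NULL, lib_b = NULL,
                          two_sided = c("minlik", "doubled")) {
  two_sided <- match.arg(two_sided)
  if (phi < 0) stop_fmt("dispersion must be non-negative")
  if (any(c(y_a, y_b) < 0)) stop_fmt("counts must be non-negative")
  lib_a <- lib_a %||% rep(1, length(y_a))
  lib_b <- lib_b %||% rep(1, length(y_b))
  geo <- exp(mean(log(c(lib_a, lib_b))))
  a <- round(sum(y_a * geo / lib_a))
  b <- round(sum(y_b * geo / lib_b))
  nb_exact_test_totals(a, b, length(y_a), length(y_b), phi, two_sided)
}

## exact test on pre-equalised group totals
nb_exact_test_totals <- function(a, b, n_a, n_b, phi, two_sided = "minlik") {
  n <- a + b
  if (n == 0) return(1)
  x <- 0:n
  if (phi == 0) {
    lp <- stats::dbinom(x, n, n_a / (n_a + n_b), log = TRUE)
  } else {
    alpha <- n_a / phi
    beta <- n_b / phi
    lp <- lchoose(n, x) + lbeta(x + alpha, n - x + beta) - lbeta(alpha, beta)
  }
  obs <- lp[a + 1L]
  if (two_sided == "minlik") {
    sel <- lp <= obs + 1e-7           # ties included within tolerance
    min(1, sum(exp(lp[sel])) / sum(exp(lp)))
  } else {
    lo <- sum(exp(lp[x <= a])); hi <- sum(exp(lp[x >= a]))
    min(1, 2 * min(lo, hi))
  }
}

#' Per-replicate fold change and its standard error from CPM values
#'
#' Replicates are paired by index; for each pair r the log2 ratio
#' `log2(mut_r / wt_r)` is computed, and the mean and standard error of the
#' mean (sd / sqrt(n)) over replicates are returned.
#'
#' @param wt_cpm,mut_cpm positive (prior-adjusted) CPM vectors or matrices
#'   (genes x replicates) paired by column index.
#' @return list (vectors when matrices are supplied) with `log2fc_mean`
#'   and `log2fc_sem`.
#' @export
fc_sem_from_replicates <- function(wt_cpm, mut_cpm) {
  if (is.null(dim(wt_cpm))) wt_cpm <- matrix(wt_cpm, nrow = 1)
  if (is.null(dim(mut_cpm))) mut_cpm <- matrix(mut_cpm, nrow = 1)
  wt_cpm <- as.matrix(wt_cpm); mut_cpm <- as.matrix(mut_cpm)
  if (!identical(dim(wt_cpm), dim(mut_cpm)))
    stop_fmt("wild-type and mutant CPM matrices must have identical dimensions")
  l <- log2(mut_cpm / wt_cpm)
  n <- ncol(l)
  m <- rowMeans(l)
  sem <- if (n > 1) apply(l, 1, stats::sd) / sqrt(n) else rep(NA_real_, nrow(l))
  list(log2fc_mean = m, log2fc_sem = sem)
}

#' Flag differentially expressed transcripts
#'
#' A transcript is DE when `|log2fc_mean| > log2(fc)` and
#' `bh_adjusted_p < q` (both strict). When `min_log2_cpm` is supplied an
#' additional logical column `go_eligible` marks DE transcripts that also
#' pass the expression filter `mean_log2_cpm > min_log2_cpm` (the GO-input
#' variant).
#'
#' @param results data.frame with `log2fc_mean`, `bh_adjusted_p` and
#'   (for the filter) `mean_log2_cpm` columns.
#' @param fc fold-change cutoff (default 1.5).
#' @param q BH-adjusted p cutoff (default 0.01).
#' @param min_log2_cpm optional log2 CPM expression filter.
#' @return the input with `is_de`, `direction` (and possibly
#'   `go_eligible`) columns appended.
#' @export
call_de_transcripts <- function(results, fc = 1.5, q = 0.01,
                                min_log2_cpm = NULL) {
  is_de <- !is.na(results$bh_adjusted_p) &
    abs(results$log2fc_mean) > log2(fc) & results$bh_adjusted_p < q
  results$is_de <- is_de
  results$direction <- ifelse(!is_de, "none",
                              ifelse(results$log2fc_mean > 0, "over", "under"))
  if (!is.null(min_log2_cpm))
    results$go_eligible <- is_de & results$mean_log2_cpm > min_log2_cpm
  results
}

#' Full count-based differential-expression analysis for one mutant
#'
#' Runs TMM normalisation on the mutant + wild-type samples, estimates a
#' common dispersion, applies the conditional NB exact test per gene,
#' adjusts p-values by Benjamini-Hochberg, computes replicate-paired fold
#' changes with SEM from prior-adjusted CPM, and flags DE transcripts.
#'
#' @param counts integer matrix genes x samples.
#' @param samples data.frame with columns `sample` and `condition` matching
#'   the count columns.
#' @param mutant,wt condition labels to compare.
#' @param fc,q DE thresholds, see [call_de_transcripts()].
#' @param min_log2_cpm optional GO-input expression filter.
#' @param prior CPM prior count for logs and ratios (default 0.5).
#' @param dispersion optional fixed dispersion; estimated when `NULL`.
#' @param two_sided tail convention of the exact test.
#' @return data.frame with one row per gene: `gene_id`, `log2fc_mean`,
#'   `log2fc_sem`, `p_value`, `bh_adjusted_p`, `mean_log2_cpm`, `is_de`,
#'   `direction` (plus `go_eligible` when filtered).
#' @export
rnaseq_de <- function(counts, samples, mutant, wt = "wt", fc = 1.5, q = 0.01,
                      min_log2_cpm = NULL, prior = 0.5, dispersion = NULL,
                      two_sided = "minlik") {
  counts <- as.matrix(counts)
  sel <- samples$condition %in% c(mutant, wt)
  if (!any(samples$condition == mutant)) stop_fmt("no samples for condition '%s'", mutant)
  if (!any(samples$condition == wt)) stop_fmt("no samples for condition '%s'", wt)
  smp <- samples[sel, , drop = FALSE]
  y <- counts[, smp$sample, drop = FALSE]
  f <- tmm_factors(y)
  eff <- colSums(y) * f
  grp <- ifelse(smp$condition == mutant, "mut", "wt")
  phi <- dispersion %||% estimate_common_dispersion(y, grp, eff_lib = eff)
  ja <- which(grp == "mut"); jb <- which(grp == "wt")
  geo <- exp(mean(log(eff)))
  # equalise once, test each gene on rounded group totals
  ya <- round(sweep(y[, ja, drop = FALSE], 2, geo / eff[ja], "*"))
  yb <- round(sweep(y[, jb, drop = FALSE], 2, geo / eff[jb], "*"))
  p <- vapply(seq_len(nrow(y)), function(i) {
    nb_exact_test_totals(sum(ya[i, ]), sum(yb[i, ]), length(ja), length(jb),
                         phi, two_sided)
  }, numeric(1))
  padj <- bh_adjust(p)
  cp <- cpm(y, factors = f)
  if (length(ja) == length(jb)) {
    fcres <- fc_sem_from_replicates(cp[, jb, drop = FALSE] + prior,
                                    cp[, ja, drop = FALSE] + prior)
  } else {
    # unbalanced design: group-mean ratio, SEM unavailable
    fcres <- list(log2fc_mean = log2((rowMeans(cp[, ja, drop = FALSE]) + prior) /
                                     (rowMeans(cp[, jb, drop = FALSE]) + prior)),
                  log2fc_sem = rep(NA_real_, nrow(y)))
  }
  res <- data.frame(gene_id = rownames(y),
                    log2fc_mean = fcres$log2fc_mean,
                    log2fc_sem = fcres$log2fc_sem,
                    p_value = p,
                    bh_adjusted_p = padj,
                    mean_log2_cpm = rowMeans(log2(cp + prior)),
                    row.names = NULL, stringsAsFactors = FALSE)
  call_de_transcripts(res, fc = fc, q = q, min_log2_cpm = min_log2_cpm)
}
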