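## Gene-class (oogenic / spermatogenic / gender-neutral) profiling:
## fold-change distribution tests, observed/expected class enrichment in
## the over- and underexpressed sets, and cross-omics correlation.

#' Two-sample Kolmogorov-Smirnov test of a class against the rest
#'
#' Compares the log2 fold-change distribution of one gene class against all
#' other features with a two-sided two-sample KS test. The exact p-value is
#' used when the combined sample size is below 30, the asymptotic
#' distribution otherwise; ties are handled by taking the supremum of the
#' ECDF difference over the observed points.
#'
#' @param log2fc numeric vector of fold changes.
#' @param class_label character/factor vector of class labels, same length.
#' @param class the class to test against its complement.
#' @return list with elements `D` (statistic in `[0, 1]`), `p_value`,
#'   `n_class` and `n_other`.
#' @export
ks_class_test <- function(log2fc, class_label, class) {
  if (length(log2fc) != length(class_label))
    stop_fmt("log2fc and class_label lengths differ")
  x <- log2fc[class_label == class]
  y <- log2fc[class_label != class]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x)) stop_fmt("class '%s' is empty", class)
  if (!length(y)) stop_fmt("complement of class '%s' is empty", class)
  exact <- (length(x) + length(y)) < 30
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided",
                                        exact = exact))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n_class = length(x), n_other = length(y))
}

#' Observed vs expected class counts in a DE direction set
#'
#' For each gene class, compares the observed number of class members in
#' the over- or underexpressed set against the expectation
#' `|direction set| * class frequency in the universe`, reporting
#' `log2(observed / expected)` and a two-tailed Fisher's exact test on
#' `[[class & set, class & !set], [other & set, other & !set]]`.
#'
#' @param class_label character vector of class labels over the universe.
#' @param de_direction character vector (`"over"`, `"under"`, `"none"`),
#'   same length.
#' @param direction which DE set to profile: `"over"` or `"under"`.
#' @return data.frame: `class`, `class_total`, `observed`, `expected`,
#'   `log2_obs_over_exp` (`NA` when expected is 0; `-Inf` when the class is
#'   absent from a non-empty direction set), `p_fisher_two_tailed`.
#' @export
obs_exp_enrichment <- function(class_label, de_direction,
                               direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (length(class_label) != length(de_direction))
    stop_fmt("class_label and de_direction lengths differ")
  in_set <- de_direction == direction
  n_set <- sum(in_set)
  n <- length(class_label)
  rows <- lapply(sort(unique(class_label)), function(cl) {
    is_cl <- class_label == cl
    obs <- sum(is_cl & in_set)
    exp <- n_set * sum(is_cl) / n
    p <- fisher_two_tailed(obs, sum(is_cl) - obs,
                           n_set - obs, n - sum(is_cl) - n_set + obs)
    data.frame(class = cl, class_total = sum(is_cl), observed = obs,
               expected = exp,
               log2_obs_over_exp = if (exp == 0) NA_real_ else log2(obs / exp),
               p_fisher_two_tailed = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-omics fold-change correlation
#'
#' Matches protein-group and transcript results by feature id and reports
#' the Pearson correlation of their log2 fold changes, overall and within
#' the four significance categories (significant at neither level, protein
#' only, transcript only, or both).
#'
#' @param protein_res data.frame with columns `protein_group_id`,
#'   `log2fc_mean`, `is_de` (from [silac_de()]).
#' @param transcript_res data.frame with columns `gene_id`, `log2fc_mean`,
#'   `is_de` (from [rnaseq_de()]).
#' @return data.frame: `category`, `n`, `pearson_r` (`NA` with fewer than 2
#'   matched pairs).
#' @export
omics_correlation <- function(protein_res, transcript_res) {
  m <- merge(protein_res[, c("protein_group_id", "log2fc_mean", "is_de")],
             transcript_res[, c("gene_id", "log2fc_mean", "is_de")],
             by.x = "protein_group_id", by.y = "gene_id",
             suffixes = c("_protein", "_transcript"))
  if (nrow(m) < 2) stop_fmt("fewer than 2 features matched across omics layers")
  cat_of <- function(p, t) {
    ifelse(p & t, "both", ifelse(p, "protein_only",
                                 ifelse(t, "transcript_only", "neither")))
  }
  m$category <- cat_of(m$is_de_protein, m$is_de_transcript)
  one <- function(sub, label) {
    r <- if (nrow(sub) >= 2)
      stats::cor(sub$log2fc_mean_protein, sub$log2fc_mean_transcript) else
        NA_real_
    data.frame(category = label, n = nrow(sub), pearson_r = r,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(m, "all"),
               do.call(rbind, lapply(c("neither", "protein_only",
                                       "transcript_only", "both"),
                                     function(cl) one(m[m$category == cl, ], cl))))
  rownames(out) <- NULL
  out
}
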