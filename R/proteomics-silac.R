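## Spike-in SILAC downstream analysis: proteinGroups parsing, deconvoluted
## ("ratio of ratio") quantification, median scaling, one-sample t-tests
## and DE calling.
##
## Sign convention: the deconvoluted ratio (H/L)_wt / (H/L)_mut equals
## light_mut / light_wt because the heavy channel is the common spike-in
## reference, so its log2 is already oriented mutant-relative-to-wild-type.
## All reported log2 fold changes use that orientation.

#' Construct a ratio table
#'
#' Validated container for normalised H/L ratios of protein groups across
#' `<condition>_<replicate>` experiments, plus summed H and L intensities.
#'
#' @param id character vector of unique protein-group identifiers.
#' @param ratio numeric matrix (proteins x experiments) of positive
#'   normalised H/L ratios; `NA` marks missing quantification. Column names
#'   must follow `<condition>_<replicate>`.
#' @param intensity_h,intensity_l optional numeric vectors of summed heavy
#'   and light intensities per protein group.
#' @return object of class `ratio_table`.
#' @export
ratio_table <- function(id, ratio, intensity_h = NULL, intensity_l = NULL) {
  if (anyDuplicated(id)) stop_fmt("protein group ids must be unique")
  if (!is.matrix(ratio) || nrow(ratio) != length(id))
    stop_fmt("ratio must be a matrix with one row per protein group")
  bad <- which(!is.na(ratio) & ratio <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop_fmt("non-positive H/L ratio for protein group '%s' (experiment %s)",
             id[bad[1, 1]], colnames(ratio)[bad[1, 2]])
  rownames(ratio) <- id
  structure(list(id = id, ratio = ratio,
                 intensity_h = intensity_h, intensity_l = intensity_l,
                 experiments = colnames(ratio)),
            class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("ratio_table: %d protein groups x %d experiments (%s)\n",
              length(x$id), ncol(x$ratio),
              paste(x$experiments, collapse = ", ")))
  invisible(x)
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated `proteinGroups.txt` dialect: ratio columns named
#' `Ratio H/L normalized <experiment>`, flag columns `Reverse` and
#' `Potential contaminant` using `"+"`. Decoy (reversed) and contaminant
#' protein groups are removed; missing ratio cells are preserved as `NA`.
#'
#' @param path path to the TSV file.
#' @param id_column identifier column name (default `"Protein IDs"`).
#' @return a [ratio_table()].
#' @export
read_protein_groups <- function(path, id_column = "Protein IDs") {
  tbl <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", "NaN", ""))
  if (!id_column %in% names(tbl))
    stop_fmt("mandatory column '%s' absent from %s", id_column, path)
  ratio_cols <- grep("^Ratio H/L normalized ", names(tbl), value = TRUE)
  if (!length(ratio_cols))
    stop_fmt("no 'Ratio H/L normalized <experiment>' columns found in %s", path)
  keep <- rep(TRUE, nrow(tbl))
  if ("Reverse" %in% names(tbl))
    keep <- keep & !(tbl$Reverse %in% "+")
  if ("Potential contaminant" %in% names(tbl))
    keep <- keep & !(tbl$`Potential contaminant` %in% "+")
  tbl <- tbl[keep, , drop = FALSE]
  ratio <- as.matrix(tbl[, ratio_cols, drop = FALSE])
  storage.mode(ratio) <- "double"
  colnames(ratio) <- sub("^Ratio H/L normalized ", "", ratio_cols)
  bad <- which(!is.na(ratio) & ratio <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop_fmt("non-positive ratio in row '%s' of %s",
             tbl[[id_column]][bad[1, 1]], path)
  ratio_table(id = tbl[[id_column]], ratio = ratio,
              intensity_h = if ("Intensity H" %in% names(tbl)) tbl$`Intensity H`,
              intensity_l = if ("Intensity L" %in% names(tbl)) tbl$`Intensity L`)
}

#' Heavy-label incorporation efficiency
#'
#' QC statistic for the heavy spike-in reference:
#' `100 * H / (L + H)` per cent.
#'
#' @param intensity_h,intensity_l non-negative heavy and light intensities
#'   (vectorised).
#' @return percentage in `[0, 100]`.
#' @examples
#' incorporation_efficiency(9e6, 1e6)  # 90
#' @export
incorporation_efficiency <- function(intensity_h, intensity_l) {
  if (any(intensity_h < 0 | intensity_l < 0, na.rm = TRUE))
    stop_fmt("intensities must be non-negative")
  tot <- intensity_h + intensity_l
  if (any(tot == 0, na.rm = TRUE))
    stop_fmt("incorporation efficiency undefined when both intensities are zero")
  100 * intensity_h / tot
}

#' Deconvoluted (ratio-of-ratio) protein quantification
#'
#' For each protein and replicate r computes
#' `d_r = (H/L)_wt,r / (H/L)_mut,r`; `d_r` is missing when either input is.
#' Replicates are paired by index: column r of the wild-type matrix with
#' column r of the mutant matrix. Proteins with fewer than `min_replicates`
#' non-missing deconvoluted ratios are dropped.
#'
#' @param wt_ratios,mut_ratios numeric matrices (proteins x replicates) of
#'   H/L ratios with identical row order; column names, when present on
#'   both, must pair up as `<condition>_<r>` with matching replicate tags.
#' @param min_replicates minimum non-missing deconvoluted ratios required
#'   to retain a protein (default 2).
#' @return numeric matrix of deconvoluted ratios for retained proteins;
#'   attribute `"dropped"` lists removed protein ids.
#' @export
deconvolute <- function(wt_ratios, mut_ratios, min_replicates = 2) {
  wt_ratios <- as.matrix(wt_ratios); mut_ratios <- as.matrix(mut_ratios)
  if (!identical(dim(wt_ratios), dim(mut_ratios)))
    stop_fmt("wild-type and mutant ratio matrices must have identical dimensions")
  if (!is.null(rownames(wt_ratios)) && !is.null(rownames(mut_ratios)) &&
      !identical(rownames(wt_ratios), rownames(mut_ratios)))
    stop_fmt("wild-type and mutant tables list proteins in different orders")
  wr <- replicate_tags(colnames(wt_ratios))
  mr <- replicate_tags(colnames(mut_ratios))
  if (!is.null(wr) && !is.null(mr) && !identical(wr, mr))
    stop_fmt("replicate labels do not pair up: wt (%s) vs mutant (%s)",
             paste(wr, collapse = ","), paste(mr, collapse = ","))
  d <- wt_ratios / mut_ratios
  colnames(d) <- if (!is.null(wr)) paste0("rep_", wr) else
    paste0("rep_", seq_len(ncol(d)))
  n_ok <- rowSums(!is.na(d))
  keep <- n_ok >= min_replicates
  out <- d[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(d)[!keep]
  out
}

replicate_tags <- function(cn) {
  if (is.null(cn)) return(NULL)
  sub("^.*_", "", cn)
}

#' Median-scale deconvoluted ratios and test against no change
#'
#' Scales each replicate column so its median across proteins equals 1
#' (`scaling = "per_replicate"`, the default spike-in correction) or scales
#' all columns by the single pooled median (`scaling = "pooled"`), log2
#' transforms, and per protein reports the mean of available log2 values
#' and the two-sided one-sample t-test p-value against 0 with `n - 1`
#' degrees of freedom. Proteins whose log2 values have zero variance get an
#' undefined (`NA`) p-value, never 0 or 1.
#'
#' @param d matrix of deconvoluted ratios (proteins x replicates) as
#'   returned by [deconvolute()].
#' @param scaling `"per_replicate"` or `"pooled"`.
#' @return data.frame with columns `protein_group_id`, `n_replicates_used`,
#'   `log2fc_mean`, `p_value`.
#' @export
scale_and_test <- function(d, scaling = c("per_replicate", "pooled")) {
  scaling <- match.arg(scaling)
  d <- as.matrix(d)
  all_na <- colSums(!is.na(d)) == 0L
  if (any(all_na)) {
    warning(sprintf("dropping all-missing replicate column(s): %s",
                    paste(colnames(d)[all_na], collapse = ", ")))
    d <- d[, !all_na, drop = FALSE]
  }
  if (ncol(d) == 0L)
    return(data.frame(protein_group_id = character(),
                      n_replicates_used = integer(),
                      log2fc_mean = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  if (scaling == "per_replicate") {
    med <- apply(d, 2, stats::median, na.rm = TRUE)
    d <- sweep(d, 2, med, "/")
  } else {
    d <- d / stats::median(d, na.rm = TRUE)
  }
  l <- log2(d)
  n <- rowSums(!is.na(l))
  m <- rowMeans(l, na.rm = TRUE)
  s <- apply(l, 1, stats::sd, na.rm = TRUE)
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  p[!is.na(s) & s == 0] <- NA_real_   # zero variance: p undefined
  data.frame(protein_group_id = rownames(d) %||% as.character(seq_len(nrow(d))),
             n_replicates_used = as.integer(n),
             log2fc_mean = m, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag differentially expressed protein groups
#'
#' A protein is DE when `|log2fc_mean| > log2(fc_cutoff)` and
#' `p_value < p_cutoff` (both strict). Proteins with an undefined p-value
#' are never DE.
#'
#' @param results data.frame from [scale_and_test()].
#' @param fc_cutoff fold-change cutoff on the natural scale (default 1.5).
#' @param p_cutoff p-value cutoff (default 0.05).
#' @return the input with logical `is_de` and `direction`
#'   (`"over"`/`"under"`/`"none"`) columns appended.
#' @export
call_de_proteins <- function(results, fc_cutoff = 1.5, p_cutoff = 0.05) {
  is_de <- !is.na(results$p_value) &
    abs(results$log2fc_mean) > log2(fc_cutoff) &
    results$p_value < p_cutoff
  results$is_de <- is_de
  results$direction <- ifelse(!is_de, "none",
                              ifelse(results$log2fc_mean > 0, "over", "under"))
  results
}

#' Full SILAC differential-expression analysis for one mutant
#'
#' Convenience wrapper: extracts the wild-type and mutant experiment
#' columns from a [ratio_table()], deconvolutes, median-scales, tests and
#' flags DE protein groups.
#'
#' @param rt a [ratio_table()].
#' @param mutant,wt condition labels; experiments named
#'   `<condition>_<replicate>` are selected.
#' @param fc_cutoff,p_cutoff DE thresholds, see [call_de_proteins()].
#' @param scaling see [scale_and_test()].
#' @param min_replicates see [deconvolute()].
#' @return data.frame of per-protein results (id, n, log2fc, p, DE flag,
#'   direction).
#' @export
silac_de <- function(rt, mutant, wt = "wt", fc_cutoff = 1.5, p_cutoff = 0.05,
                     scaling = "per_replicate", min_replicates = 2) {
  stopifnot(inherits(rt, "ratio_table"))
  wt_cols <- grep(sprintf("^%s_", wt), rt$experiments, value = TRUE)
  mut_cols <- grep(sprintf("^%s_", mutant), rt$experiments, value = TRUE)
  if (!length(wt_cols)) stop_fmt("no experiments found for condition '%s'", wt)
  if (!length(mut_cols)) stop_fmt("no experiments found for condition '%s'", mutant)
  d <- deconvolute(rt$ratio[, wt_cols, drop = FALSE],
                   rt$ratio[, mut_cols, drop = FALSE],
                   min_replicates = min_replicates)
  res <- scale_and_test(d, scaling = scaling)
  call_de_proteins(res, fc_cutoff = fc_cutoff, p_cutoff = p_cutoff)
}
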