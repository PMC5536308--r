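## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple testing by controlling the
#' false discovery rate: p-values are sorted in ascending order, the i-th
#' order statistic is replaced by `min_{j >= i} p_(j) * m / j` (capped at 1)
#' and the result is mapped back to the input order. `NA` entries are
#' passed through and do not count towards `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return numeric vector of the same length with adjusted p-values.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.005))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_fmt("p-values must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_fmt("p-values must lie in [0, 1]")
  out <- p
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  # cummin over descending order implements the step-up minimum over j >= i
  out[ok] <- pmin(1, cummin(pv[o] * m / seq(m, 1L)))[ro]
  out
}

## deterministic child seed derivation; keeps results below .Machine$integer.max
child_seed <- function(seed, offset) {
  (as.integer(seed) + 1000L * as.integer(offset)) %% 2147483647L
}

## write a data.frame as TSV with optional "# key: value" provenance header
write_tsv_commented <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6L)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
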