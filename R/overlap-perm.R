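## Permutation significance of Venn-region overlaps between per-condition
## significant-feature sets. The null model redraws, for every condition
## independently, a uniform random subset of that condition's universe with
## the same cardinality as the observed significant set, and recomputes the
## region counts; per region it reports the permutation median, the 2.5-97.5
## percentile range, log2(observed / median) and a two-sided add-one
## empirical p-value.

#' Construct an overlap input
#'
#' @param universes named list (one element per condition, k in 2..5) of
#'   feature-id vectors quantified in that condition.
#' @param significant named list of significant-feature subsets, same names.
#' @return object of class `overlap_input`.
#' @export
overlap_input <- function(universes, significant) {
  if (is.null(names(universes)) || !identical(names(universes), names(significant)))
    stop_fmt("universes and significant sets must share condition names")
  k <- length(universes)
  if (k < 2) stop_fmt("at least two conditions required")
  universes <- lapply(universes, unique)
  significant <- lapply(significant, unique)
  for (cond in names(universes)) {
    extra <- setdiff(significant[[cond]], universes[[cond]])
    if (length(extra))
      stop_fmt("condition '%s': %d significant feature(s) outside its universe",
               cond, length(extra))
  }
  structure(list(conditions = names(universes), universes = universes,
                 significant = significant), class = "overlap_input")
}

## restrict to the intersection universe when requested; returns the
## feature pool per condition and the significant sets to count
prepare_overlap <- function(input, universe_mode) {
  if (universe_mode == "intersection") {
    common <- Reduce(intersect, input$universes)
    if (!length(common))
      stop_fmt("intersection of condition universes is empty")
    list(universes = stats::setNames(rep(list(common), length(input$conditions)),
                                     input$conditions),
         significant = lapply(input$significant, intersect, common))
  } else {
    list(universes = input$universes, significant = input$significant)
  }
}

## region counts from a named list of sets (features assigned to exactly
## one region by membership pattern)
region_counts_sets <- function(sets) {
  k <- length(sets)
  feats <- unique(unlist(sets, use.names = FALSE))
  rn <- region_names(names(sets))
  if (!length(feats))
    return(stats::setNames(integer(length(rn)), rn))
  code <- integer(length(feats))
  for (i in seq_len(k))
    code <- code + bitwShiftL(1L, i - 1L) * (feats %in% sets[[i]])
  stats::setNames(tabulate(code, nbins = 2^k - 1L), rn)
}

#' Observed Venn-region counts
#'
#' Assigns every significant feature to exactly one of the `2^k - 1` Venn
#' regions by its membership pattern across the k significant sets. In
#' `"intersection"` mode features are first restricted to the intersection
#' of the condition universes (an empty intersection is an error); in
#' `"per-condition"` mode each set is counted over its own universe.
#'
#' @param input an [overlap_input()].
#' @param universe_mode `"intersection"` (default) or `"per-condition"`.
#' @return named integer vector of region counts (names as in
#'   [region_names()]).
#' @export
venn_regions <- function(input, universe_mode = c("intersection", "per-condition")) {
  stopifnot(inherits(input, "overlap_input"))
  universe_mode <- match.arg(universe_mode)
  prep <- prepare_overlap(input, universe_mode)
  region_counts_sets(prep$significant)
}

#' Permutation null distribution of Venn-region counts
#'
#' Each of the `B` iterations draws, independently for every condition, a
#' uniform random subset of that condition's universe with the cardinality
#' of its observed significant set, and recomputes all region counts.
#' Per region the summary reports the observed count, the permutation
#' median and 2.5/97.5 percentiles, `log2(observed / median)` (`NA` when
#' the median is 0; `-Inf` when the observed count is 0 and the median
#' positive) and the two-sided add-one empirical p-value
#' `p_pt = min(1, 2 * min(G, L) / (B + 1))` with
#' `G = 1 + #[perm >= obs]`, `L = 1 + #[perm <= obs]`, which is never 0.
#'
#' @param input an [overlap_input()].
#' @param B number of permutation iterations (default 10000).
#' @param seed integer seed for reproducibility.
#' @param universe_mode see [venn_regions()].
#' @param keep_perm attach the full B x regions permutation count matrix as
#'   attribute `"perm"` (default `FALSE`).
#' @return data.frame of class `overlap_perm_result`, one row per region:
#'   `region`, `observed`, `perm_median`, `perm_p2_5`, `perm_p97_5`,
#'   `log2_obs_over_median`, `p_pt`.
#' @export
permutation_null <- function(input, B = 10000, seed = NULL,
                             universe_mode = c("intersection", "per-condition"),
                             keep_perm = FALSE) {
  stopifnot(inherits(input, "overlap_input"))
  universe_mode <- match.arg(universe_mode)
  if (B < 1) stop_fmt("B must be at least 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  prep <- prepare_overlap(input, universe_mode)
  observed <- region_counts_sets(prep$significant)
  k <- length(prep$universes)
  feats <- unique(unlist(prep$universes, use.names = FALSE))
  nf <- length(feats)
  pool <- lapply(prep$universes, function(u) match(u, feats))
  sizes <- lengths(prep$significant)
  nr <- 2^k - 1L
  perm <- matrix(0L, B, nr, dimnames = list(NULL, names(observed)))
  code <- integer(nf)
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  for (b in seq_len(B)) {
    code[] <- 0L
    for (i in seq_len(k)) {
      if (sizes[i] > 0L) {
        drawn <- pool[[i]][sample.int(length(pool[[i]]), sizes[i])]
        code[drawn] <- code[drawn] + bits[i]
      }
    }
    perm[b, ] <- tabulate(code, nbins = nr)
  }
  med <- apply(perm, 2, stats::median)
  q <- apply(perm, 2, stats::quantile, probs = c(0.025, 0.975))
  g <- 1 + colSums(perm >= rep(observed, each = B))
  l <- 1 + colSums(perm <= rep(observed, each = B))
  p_pt <- pmin(1, 2 * pmin(g, l) / (B + 1))
  lr <- ifelse(med == 0, NA_real_, log2(observed / med))
  out <- data.frame(region = names(observed),
                    observed = as.integer(observed),
                    perm_median = med, perm_p2_5 = q[1, ], perm_p97_5 = q[2, ],
                    log2_obs_over_median = lr, p_pt = p_pt,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("overlap_perm_result", "data.frame")
  if (keep_perm) attr(out, "perm") <- perm
  out
}

#' Closed-form expected Venn-region counts under independence
#'
#' For sets of sizes `k_1..k_m` drawn independently and uniformly from a
#' common universe of size `N`, the expected count of the region containing
#' exactly the conditions in S is
#' `N * prod_{i in S}(k_i / N) * prod_{i not in S}(1 - k_i / N)`.
#'
#' @param sizes named numeric vector of set sizes (`k_i <= N`).
#' @param N universe size.
#' @return named numeric vector of expected counts per region.
#' @examples
#' expected_overlap_closed_form(c(A = 10, B = 20, C = 30), N = 100)
#' @export
expected_overlap_closed_form <- function(sizes, N) {
  if (any(sizes > N)) stop_fmt("set sizes must not exceed the universe size")
  if (any(sizes < 0) || N < 1) stop_fmt("sizes must be non-negative, N positive")
  k <- length(sizes)
  labs <- names(sizes) %||% LETTERS[seq_len(k)]
  p_in <- sizes / N
  vapply(seq_len(2^k - 1L), function(code) {
    members <- bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) > 0L
    N * prod(p_in[members]) * prod(1 - p_in[!members])
  }, numeric(1)) |> stats::setNames(region_names(labs))
}

#' Exhaustive null distribution of the all-conditions overlap (oracle)
#'
#' Enumerates every combination of fixed-size subsets of a common universe
#' and tabulates the size of their full intersection. Exponential in
#' problem size: intended as an independent oracle for tiny cases
#' (`choose(N, k)^m` combinations).
#'
#' @param sizes vector of subset sizes.
#' @param N universe size (<= 7 enforced).
#' @return named numeric vector: probability of each possible full
#'   intersection size `0..min(sizes)`.
#' @export
exhaustive_overlap_null <- function(sizes, N) {
  if (N > 7) stop_fmt("exhaustive enumeration restricted to N <= 7")
  subsets <- lapply(sizes, function(s) utils::combn(N, s, simplify = FALSE))
  idx <- do.call(expand.grid, lapply(subsets, seq_along))
  counts <- integer(min(sizes) + 1L)
  for (r in seq_len(nrow(idx))) {
    inter <- Reduce(intersect, Map(function(ss, i) ss[[i]], subsets, idx[r, ]))
    counts[length(inter) + 1L] <- counts[length(inter) + 1L] + 1L
  }
  stats::setNames(counts / sum(counts), 0:min(sizes))
}
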