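## GO term enrichment/depletion on an acyclic is-a term graph: evidence-code
## filtering, true-path propagation, two-tailed Fisher's exact test and the
## elim decorrelation algorithm (children tested before parents; genes of
## significant children removed before ancestors are tested).

#' Construct a GO DAG
#'
#' Builds a validated directed acyclic term graph from a child -> parent
#' edge list. Acyclicity is checked by topological sort; term depth is the
#' longest path to the root (roots have depth 0).
#'
#' @param edges data.frame with columns `child` and `parent` (and
#'   optionally `ontology`); edges point from the more specific term to its
#'   parent.
#' @param terms optional character vector of term ids (isolated roots can
#'   be listed here even without edges).
#' @return object of class `go_dag` with elements `terms`, `parents`
#'   (named list), `children` (named list), `depth` (named integer) and
#'   `roots`.
#' @export
go_dag <- function(edges, terms = NULL) {
  if (nrow(edges) && !all(c("child", "parent") %in% names(edges)))
    stop_fmt("edges must have 'child' and 'parent' columns")
  all_terms <- unique(c(terms, edges$child, edges$parent))
  if (!length(all_terms)) stop_fmt("empty DAG")
  parents <- split(edges$parent, factor(edges$child, levels = all_terms))
  children <- split(edges$child, factor(edges$parent, levels = all_terms))
  # Kahn topological sort over child -> parent edges (parents come last)
  out_deg <- lengths(parents)                 # edges leaving each child
  order <- character(0)
  incoming <- children                        # parent -> children
  active <- names(out_deg)[out_deg == 0L]     # roots first
  remaining <- out_deg
  while (length(active)) {
    t <- active[1]; active <- active[-1]
    order <- c(order, t)
    for (ch in incoming[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) active <- c(active, ch)
    }
  }
  if (length(order) != length(all_terms))
    stop_fmt("term graph contains a cycle involving: %s",
             paste(setdiff(all_terms, order), collapse = ", "))
  depth <- stats::setNames(integer(length(all_terms)), all_terms)
  for (t in order) {                          # roots processed first
    ps <- parents[[t]]
    if (length(ps)) depth[t] <- max(depth[ps]) + 1L
  }
  roots <- all_terms[lengths(parents) == 0L]
  structure(list(terms = all_terms, parents = parents, children = children,
                 depth = depth, roots = roots), class = "go_dag")
}

#' Read a GO DAG from an edge-list TSV
#'
#' @param path TSV with header columns `child`, `parent` and optionally
#'   `ontology`.
#' @param ontology optional ontology label to subset to before building.
#' @return a [go_dag()].
#' @export
read_go_dag <- function(path, ontology = NULL) {
  edges <- read_tsv_plain(path)
  if (!is.null(ontology) && "ontology" %in% names(edges))
    edges <- edges[edges$ontology == ontology, , drop = FALSE]
  go_dag(edges)
}

#' All ancestors of each term
#'
#' @param dag a [go_dag()].
#' @return named list mapping every term to the character vector of its
#'   ancestors (excluding itself).
#' @export
go_ancestors <- function(dag) {
  stopifnot(inherits(dag, "go_dag"))
  anc <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  order <- names(sort(dag$depth))             # shallow terms first
  for (t in order) {
    ps <- dag$parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Filter annotations by evidence code
#'
#' Drops (gene, term, evidence_code) triples whose code is in the excluded
#' set; by default removes ND (no biological data), IEA (electronic) and NR
#' (not recorded) annotations.
#'
#' @param annotations data.frame with columns `gene`, `term`,
#'   `evidence_code`.
#' @param exclude character vector of codes to drop.
#' @return the filtered data.frame.
#' @export
filter_evidence <- function(annotations, exclude = c("ND", "IEA", "NR")) {
  if (!all(c("gene", "term") %in% names(annotations)))
    stop_fmt("annotations must have 'gene' and 'term' columns")
  if (!length(exclude) || !"evidence_code" %in% names(annotations))
    return(annotations)
  out <- annotations[!(annotations$evidence_code %in% exclude), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Propagate annotations up the DAG (true-path rule)
#'
#' Closes the gene -> term map under ancestors: a gene annotated to a term
#' becomes annotated to all of that term's ancestors. Idempotent; terms in
#' the annotation that are absent from the DAG are dropped with a warning.
#'
#' @param dag a [go_dag()].
#' @param annotations data.frame with columns `gene` and `term`.
#' @return data.frame with columns `gene` and `term`, unique pairs.
#' @export
propagate_annotations <- function(dag, annotations) {
  stopifnot(inherits(dag, "go_dag"))
  unknown <- setdiff(unique(annotations$term), dag$terms)
  if (length(unknown)) {
    warning(sprintf("dropping %d annotation term(s) absent from the DAG",
                    length(unknown)))
    annotations <- annotations[annotations$term %in% dag$terms, , drop = FALSE]
  }
  anc <- go_ancestors(dag)
  ex_terms <- lapply(annotations$term, function(t) c(t, anc[[t]]))
  out <- data.frame(
    gene = rep(annotations$gene, lengths(ex_terms)),
    term = unlist(ex_terms, use.names = FALSE),
    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables (with the observed
#' margins) whose probability does not exceed the observed table's, within
#' a relative tolerance of 1e-7 for ties.
#'
#' @param a,b,c,d non-negative integer cell counts of the table
#'   `[[a, b], [c, d]]`.
#' @return p-value in (0, 1].
#' @examples
#' fisher_two_tailed(2, 0, 0, 2)  # 1/3
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_fmt("cell counts must be non-negative integers")
  m <- a + b          # white balls: row 1
  n <- c + d          # black balls: row 2
  k <- a + c          # drawn: column 1
  x <- max(0, k - n):min(k, m)
  lp <- stats::dhyper(x, m, n, k, log = TRUE)
  obs <- stats::dhyper(a, m, n, k, log = TRUE)
  sum(exp(lp[lp <= obs + 1e-7]))
}

#' GO enrichment/depletion with the elim decorrelation algorithm
#'
#' Terms annotated (via the propagated map) to fewer than `node_size`
#' universe genes are excluded. Remaining terms are processed in order of
#' decreasing depth (children before parents; ties in lexicographic term
#' order). Each term is tested with a two-tailed Fisher's exact test on its
#' current annotated genes versus the interesting set; if the p-value falls
#' below `elim_cutoff`, the term's current genes are marked eliminated for
#' all of its ancestors, and an ancestor's test later excludes those genes
#' from its annotation, the universe and the interesting set alike, so a
#' parent whose signal came entirely from a significant child is left with
#' no evidence. With `elim_cutoff = 0` no elimination happens and the
#' result equals the classic per-term Fisher test.
#'
#' @param dag a [go_dag()].
#' @param annotations propagated annotation data.frame (`gene`, `term`);
#'   see [propagate_annotations()].
#' @param universe character vector of all quantified genes.
#' @param interesting character vector of significant genes (subset of
#'   `universe`).
#' @param node_size minimum annotated universe genes per testable term
#'   (default 10).
#' @param elim_cutoff p-value threshold triggering elimination
#'   (default 0.01).
#' @return data.frame sorted by p-value: `term`, `annotated_in_universe`
#'   (post-elimination), `significant_annotated`, `expected`,
#'   `p_fisher_two_tailed`, `direction` (`"enriched"`/`"depleted"`).
#' @export
elim_enrichment <- function(dag, annotations, universe, interesting,
                            node_size = 10, elim_cutoff = 0.01) {
  stopifnot(inherits(dag, "go_dag"))
  extra <- setdiff(interesting, universe)
  if (length(extra))
    stop_fmt("%d interesting gene(s) are not in the universe", length(extra))
  ann <- annotations[annotations$gene %in% universe, , drop = FALSE]
  gene_sets <- split(ann$gene, ann$term)
  gene_sets <- lapply(gene_sets, unique)
  testable <- names(gene_sets)[lengths(gene_sets) >= node_size]
  if (!length(testable))
    return(data.frame(term = character(), annotated_in_universe = integer(),
                      significant_annotated = integer(), expected = numeric(),
                      p_fisher_two_tailed = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  ord <- testable[order(-dag$depth[testable], testable)]
  anc <- go_ancestors(dag)
  eliminated <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  n_universe <- length(unique(universe))
  interesting <- unique(interesting)
  rows <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    t <- ord[i]
    el <- eliminated[[t]]
    cur <- setdiff(gene_sets[[t]], el)
    int_t <- setdiff(interesting, el)
    n_t <- n_universe - length(el)
    a <- length(intersect(cur, int_t))
    b <- length(cur) - a
    cc <- length(int_t) - a
    dd <- n_t - a - b - cc
    p <- fisher_two_tailed(a, b, cc, dd)
    expected <- if (n_t > 0) length(int_t) * length(cur) / n_t else NA_real_
    rows[[i]] <- data.frame(term = t, annotated_in_universe = length(cur),
                            significant_annotated = a, expected = expected,
                            p_fisher_two_tailed = p,
                            direction = if (a > expected) "enriched" else "depleted",
                            stringsAsFactors = FALSE)
    if (p < elim_cutoff && length(cur)) {
      for (up in anc[[t]])
        eliminated[[up]] <- unique(c(eliminated[[up]], cur))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_fisher_two_tailed, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
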