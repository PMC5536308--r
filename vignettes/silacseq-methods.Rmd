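---
title: "Models and methods in silacseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in silacseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacseq)
```

silacseq compares mutant and wild-type gene expression across a spike-in
SILAC proteome and a count-based RNA-seq transcriptome, and asks the
study-level question: do the mutants' differential-expression (DE) sets
overlap more (or less) than chance? This vignette documents the models,
the parameters that matter, the synthetic-data world the tests run in, and
the design choices made where the design was genuinely open. It states no
empirical result that the test suite or acceptance script does not itself
compute.

## 1. Spike-in SILAC model

One heavy-labelled reference is mixed into every light sample, so each
experiment yields a normalised H/L ratio per protein group. For replicate
$r$ the deconvoluted ratio

$$d_r = \frac{(H/L)_{\mathrm{wt},r}}{(H/L)_{\mathrm{mut},r}}
      = \frac{L_{\mathrm{mut},r}}{L_{\mathrm{wt},r}}$$

cancels the common heavy channel, so $\log_2 d_r$ is already oriented
mutant-relative-to-wild-type. This sign convention is easy to get backwards
and is therefore stated on every relevant help page.

**Processing.** Decoy ("Reverse") and contaminant rows are removed at
parse time. Replicates are paired by index (wild-type replicate $i$ with
mutant replicate $i$); a protein is retained only with $\ge 2$ non-missing
deconvoluted ratios. Each replicate column is divided by its median across
proteins (post-scaling column median exactly 1) — the standard spike-in
correction for per-replicate mixing-ratio bias. A pooled-median variant
(`scaling = "pooled"`) is provided because the choice between the two is
not determined by the downstream contract; per-replicate is the default as
the stronger bias correction. After $\log_2$ transformation each protein is
tested with a two-sided one-sample t-test against 0 with $n-1$ degrees of
freedom ($n \in \{2,3\}$ in the motivating design, so df is 1–2 and the
test is deliberately conservative). Zero-variance proteins get an
*undefined* p-value (`NA`), never 0 or 1, and are excluded from DE calls.
DE requires $|\log_2 \mathrm{FC}| > \log_2 1.5 \approx 0.585$ **and**
$p < 0.05$, both strict.

**Incorporation QC.** Heavy-label incorporation is
$100 \cdot H / (L + H)$ per cent, with both-zero intensities rejected as
undefined input.

## 2. Count-based transcriptome DE

Counts from technical sequencing runs of the same library are summed
first. Normalisation is TMM (trimmed mean of M-values): gene-wise log
ratios against a reference column, double-trimmed (30% on M, 5% on A),
averaged with delta-method precision weights, and the resulting factors
scaled to geometric mean 1. The implementation is in-package; the test
suite checks exact agreement with an established implementation on random
fixtures.

The NB exact test substitutes for a packaged count-DE fit (the upstream
study names the package it used but not the test type or dispersion
method, so numeric equality with its DE counts is out of reach and not
attempted — results are expected to correlate with, not duplicate, that
fit):

* **Dispersion.** A single common $\phi$ in
  $\mathrm{var} = \mu + \phi\mu^2$, estimated by method of moments on
  counts rescaled to the common (geometric-mean) effective library size.
  The estimator averages per-gene moment ratios
  $\hat\phi_g = \sum_{\text{groups}}(v_g - m_g\overline{1/c}) / \sum m_g^2$
  with equal weight over genes whose rescaled mean is at least 32
  (default), rather than pooling sums across genes: under a long-tailed
  baseline distribution the pooled ratio is dominated by the few largest
  genes and its sampling noise propagates directly into type-I error.
  The pooled ratio remains as a fallback when fewer than 50 genes qualify.
  $\phi = 0$ is allowed and handled as Poisson.
* **Test.** Per gene, replicate counts are equalised to the common
  effective library size, rounded, and summed per group. Conditional on
  the pooled total $n$, the group-A total follows a beta-binomial with
  parameters $(n_A/\phi,\, n_B/\phi)$ (a binomial $n_A/(n_A+n_B)$ split at
  $\phi = 0$). The two-sided p-value sums the probabilities of all
  outcomes no more probable than the observed one ("minlik", with a 1e-7
  relative tie tolerance); a doubled-tail convention is available.
  edgeR's pseudo-count quantile equalisation is intentionally *not*
  reproduced — plain rescale-and-round is documented and testable.
* **Adjustment and calls.** Benjamini–Hochberg step-up, implemented
  directly (sorted $p_{(i)} \mapsto \min_{j\ge i} p_{(j)} m / j$, capped at
  1). DE requires $|\mathrm{FC}| > 1.5$ and adjusted $p < 0.01$, strict;
  the GO-input variant additionally requires mean $\log_2 \mathrm{CPM} > 8$.

Fold changes reported to users come from replicate-paired CPM ratios
(prior count 0.5 on the CPM scale): per replicate $\log_2(\mathrm{mut}_r /
\mathrm{wt}_r)$, then mean and SEM across replicates. With unequal group
sizes the pairing is undefined and the group-mean ratio is reported with
`NA` SEM. `cpm(..., log = TRUE)` returns $\log_2(\mathrm{CPM} + 0.5)$ —
note this prior sits on the CPM scale, not the count scale.

## 3. Venn-region permutation test

For $k$ conditions each feature in scope is assigned to exactly one of the
$2^k - 1$ regions by its membership pattern across the significant sets.
The null model redraws, independently for every condition, a uniform
subset of that condition's universe with the observed cardinality — the
natural reading of "permuting DE labels" that preserves per-condition DE
counts and universes. Two universe modes exist because printed per-set
totals can refer to either: `intersection` (default; only features
quantified in all conditions) and `per-condition`. Summaries per region:
observed count, permutation median, 2.5/97.5 percentiles,
$\log_2(\mathrm{obs}/\mathrm{median})$ (`NA` when the median is 0;
$-\infty$ when only the observed count is 0), and the two-sided add-one
empirical p-value

$$P_{PT} = \min\!\left(1,\; \frac{2\min(G, L)}{B + 1}\right),\quad
G = 1 + \#\{\mathrm{perm} \ge \mathrm{obs}\},\;
L = 1 + \#\{\mathrm{perm} \le \mathrm{obs}\},$$

which can never be 0 and covers both enrichment and depletion. Two
independent oracles guard the machinery: a closed-form expectation per
region ($N \prod_{i \in S} k_i/N \prod_{i \notin S} (1 - k_i/N)$) and an
exhaustive enumeration of all subset combinations for tiny universes; the
acceptance suite requires total-variation distance $< 0.02$ against the
enumeration at $B = 50{,}000$ and 3-MC-SE agreement with the closed form
at $B = 10{,}000$.

## 4. GO enrichment with elim

Annotations are filtered by evidence code (default exclusions: ND, IEA,
NR), then closed under ancestors (true-path rule). Terms with fewer than
`node_size` (default 10) annotated universe genes are not testable. Terms
are processed in decreasing depth — depth being the *longest* path to the
root, ties broken lexicographically for determinism — each tested with a
two-tailed Fisher's exact test (minimum-likelihood tail, matching
`fisher.test`); direction is enriched/depleted by observed versus
expected count.

**The elimination rule.** When a term's p-value falls below `elim_cutoff`
(default 0.01), its current genes are *eliminated for all ancestors*:
an ancestor's later test excludes those genes from its annotation, from
the universe, and from the interesting set alike. This is deliberately
stronger than the variant that shrinks only the ancestor's annotation
while keeping the full universe margins: under the chosen semantics a
parent whose entire signal came from one significant child is left with a
degenerate margin and $p = 1$ exactly — "no evidence remains", which is
the decorrelation behaviour this package promises and tests. With
`elim_cutoff = 0` no elimination occurs and the output equals the classic
per-term Fisher test (asserted against an independent oracle).

## 5. Gene-class profiles and cross-omics correlation

Class labels (oogenic / spermatogenic / gender-neutral) are *input data*;
no attempt is made to re-derive gametogenic classifications. The KS test
of a class against its complement uses the exact two-sample p-value below
a combined $n$ of 30 and the asymptotic distribution otherwise, with ties
handled as the supremum over observed points. Observed/expected class
enrichment uses $\mathrm{expected} = |\mathrm{set}| \cdot
f_{\mathrm{class}}$ and the same two-tailed Fisher test;
$\log_2(\mathrm{obs}/\mathrm{exp})$ is $-\infty$ for a class absent from a
non-empty set and `NA` only when the set itself is empty. Pearson
correlations of matched protein/transcript fold changes are reported
overall and within the four significance categories; categories with
fewer than two pairs give `NA`.

## 6. The synthetic world (and what a green test does not establish)

The generator's defaults state the emulated design: three mutant
conditions against a common wild-type reference, three biological
replicates, 10% true DE per condition with mean $|\log_2 \mathrm{FC}| = 2$
(half up, half down, fixed magnitude), log2 H/L replicate noise sd 0.2,
10% missing ratio cells, NB dispersion 0.05, library sizes log-uniform in
$[5 \times 10^5,\, 2 \times 10^6]$, per-gene baselines log-normal
(log2 mean 7, sd 2), classes 20% oogenic / 10% spermatogenic / 70%
neutral, and a rooted random DAG per ontology. Where the emulated study
states a value (replicate count, thresholds, iteration count 10,000) the
default *is* that value; the remaining levels were chosen once as
field-typical magnitudes and not revisited.

Ground-truth DE sets can be drawn independently per condition or pinned to
an exact Venn-region specification (`overlap_spec`), which the generator
satisfies exactly — not in expectation — so the permutation machinery can
be tested against a known overlap structure. Determinism is strict:
identical configuration (including seed) gives byte-identical outputs;
each generator consumes its own child seed (seed + fixed offset) so adding
one output does not perturb the others.

What the generator does **not** emulate: peptide-level identification and
its FDR, between-protein intensity correlation, GC/length biases and
batch structure in counts, realistic GO term-size distributions, or any
decoupling of transcription and translation (protein and transcript truth
are driven by the same fold changes, which is why the synthetic
cross-omics correlation is high where real data's is weak). Green
calibration tests therefore establish that the *statistics are correct
under their own assumptions*, not that the pipeline reproduces any
particular study's counts.

## 7. Numerical conventions and degenerate inputs

* All DE thresholds are strict inequalities; $q = 0.01$ exactly is not DE.
* Undefined values (zero-variance t-test, log of 0/0) are `NA`, serialised
  as `NA` in TSV output; signed infinities are kept as `-Inf`.
* Exact-test ties are included within a relative tolerance of $10^{-7}$
  (both the beta-binomial and hypergeometric tails).
* Equalised counts are rounded to integers before the conditional test;
  totals of 0 give $p = 1$.
* An all-missing replicate column is dropped with a warning; an all-zero
  count column is an error naming the sample.
* Floats in output tables carry 6 significant digits; the run manifest
  records package version, seed, iteration count and every threshold, and
  re-running with the manifest's configuration reproduces the outputs
  byte-for-byte.

## 8. Known limitations

* The NB exact test with common dispersion will not numerically match a
  tagwise-dispersion GLM fit; it is a documented, testable substitute.
* The permutation null treats conditions as independent; correlated DE
  calling between mutants (shared wild-type replicates) is not modelled.
* The elim variant here zeroes a parent's evidence more aggressively than
  the annotation-only variant; both agree at `elim_cutoff = 0`.
* KS p-values with heavy ties at moderate $n$ fall back to the asymptotic
  approximation.
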