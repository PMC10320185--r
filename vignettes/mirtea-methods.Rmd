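---
title: "mirTEA: statistical methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirTEA: statistical methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirTEA)
```

# The problem

A microRNA (miRNA) represses the mRNAs it binds; a set of miRNAs therefore
acts on a *target set* of genes, and the biological meaning of that set is
usually read off by asking which annotated terms — GO terms, KEGG/Reactome
pathways, MSigDB signatures, PFAM families — it over-represents. mirTEA
implements that miRNA-centric enrichment engine together with three
extensions that make it context-aware: distribution testing of targeted vs
non-targeted term components against expression contexts, term-centric
discovery of candidate miRNA regulators, and miRNA-centric analysis of
pooled CRISPR knock-out selection screens.

# The core model

## Target sets

Given a query $M = \{m_1, \dots, m_q\}$ and an interaction set with target
mapping $t(m)$, the **union** target set is $\bigcup_i t(m_i)$ and the
**at-least-$n$ intersection** keeps genes with
$|\{i : g \in t(m_i)\}| \ge n$ (miRNAs compensating each other by sharing
targets). `buildTargetSet()` records per-gene provenance so every
downstream row can name its contributing miRNAs. `nRequired = 1`
degenerates to the union by definition, which the tests assert.

## Overrepresentation testing

For a term containing $K$ of the $N$ universe genes, a target set covering
$n$ universe genes and an observed overlap $k$, the classic test is the
one-sided Fisher's exact (hypergeometric upper-tail) probability

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

evaluated exactly (`phyper`), never by normal approximation. The
**universe is the term collection's annotated gene union**: enrichment is a
statement about annotated genes, and conditioning on annotation is what
practitioners of annotation-based testing expect. Target genes outside the
universe are excluded and reported. An override argument accepts any other
background (e.g. the intersection of annotated and interaction-covered
genes) since the choice is genuinely open.

## Targeting-bias correction (Wallenius)

Genes differ in their a-priori chance of appearing in any target set
(longer 3'UTRs, more binding sites, more recorded interactions). Under
such bias the central hypergeometric null is wrong in a directional way.
`walleniusTest()` replaces it with the Wallenius non-central
hypergeometric distribution: $n$ balls drawn sequentially without
replacement, in-term genes carrying sampling weight $w$ relative to the
rest. The per-term weight is estimated by `estimateBiasOdds()`:

1. order universe genes by a nonnegative bias covariate — by default the
   number of distinct miRNAs interacting with each gene, the most direct
   measure of "targeting events" available from the interaction set
   itself;
2. split into `min(10, floor(|universe|/20))` equal-count bins and take
   per-bin targeted proportions;
3. smooth the proportions by isotonic regression (direction chosen by
   fit — bias may run either way), giving a monotone probability-weighting
   function `pwf`;
4. convert the mean `pwf` over the term and over its complement into an
   odds ratio $w = \frac{\bar p_T/(1-\bar p_T)}{\bar p_U/(1-\bar p_U)}$.

Binned proportions with monotone smoothing were chosen over a spline: the
fit is simple, deterministic, testable by hand arithmetic (the test suite
carries an 8-gene spreadsheet-style example and a top-decile construction
with a closed-form expected odds), and degenerates gracefully — a constant
covariate yields a flat `pwf` and $w = 1$ exactly, making the corrected
test collapse onto the classic one, which is asserted to $10^{-9}$.
Degenerate mean probabilities are clamped to $[10^{-6}, 1-10^{-6}]$ with a
warning rather than erroring, so a fully-targeted universe still yields a
finite odds.

**Evaluation.** The pmf is computed by a forward recursion over draws
(state = in-term genes drawn so far) for $N \le 2000$, and above that by
the integral representation
$f(x) = \binom{K}{x}\binom{N-K}{n-x}\int_0^1 (1-t^{w/d})^x(1-t^{1/d})^{n-x}\,dt$
with $d$ the weight of the undrawn balls. The raw integrand is a boundary
layer at $t = 0$; the substitution $t = u^d$ turns it into a smooth
Beta-like kernel which adaptive quadrature integrates to relative error
below $10^{-8}$ (the two routes agree to ~$10^{-13}$ relative at
$N = 8000$ in the cross-check test). Unreachable recursion states are
explicitly zero-weighted so that $0 \cdot \infty$ cannot poison the DP.

## Meta-combination (per-miRNA, merged per term)

`pathwaysUnion()` tests each query miRNA's own target set against each
term and merges the per-miRNA p-values per term with Fisher's method,
$\chi^2 = -2\sum_i \ln p_i \sim \chi^2_{2k}$. Two merging policies exist
because the natural readings differ: combining **all** per-miRNA p-values
(default) is the statistically honest meta-analysis; combining **only
significant ones** (`significant_only`, `alpha = 0.05`) mirrors the
phrasing "significantly enriched instances are merged" but inflates
significance, so it is available, surfaced in the output metadata, and not
the default. A term a miRNA never touches contributes no p-value rather
than an imputed 1 in this module; terms left with no combinable p-value
are dropped with a warning. With a single p-value Fisher's method is the
identity (df = 2), which makes the single-miRNA run collapse onto plain
enrichment — asserted in the tests.

Zero p-values from exact tests at extreme configurations are clamped to
the smallest positive double (with a warning) instead of erroring:
upstream exact tests can legitimately return denormal-small values.

# Context testing

## The percent-expressing log2FC metric

For gene $g$ and context $c$ with samples $S_c$,
$p_{gc} = 100\cdot\frac{|\{s \in S_c : x_{gs} \ge \theta\}|}{|S_c|}$ and

$$\mathrm{log2FC}_{gc} = \log_2 \frac{p_{gc} + \varepsilon}
 {\mathrm{median}_{c' \ne c}(p_{gc'}) + \varepsilon}.$$

The threshold $\theta$ is one read for single-cell count matrices and
10 TPM for tissue-level matrices (a balanced estimator of consistent,
context-specific non-zero expression); `generic` mode takes a
user-supplied $\theta$. The pseudocount $\varepsilon$ (default 0.01
percentage points, configurable) is this package's own device: without it
a gene silent in the remaining contexts divides by zero. It is symmetric —
a gene at 0% everywhere gets exactly 0 — and small enough to be invisible
at biologically meaningful percentages. The metric is invariant to sample
order and to permutation of the non-focal contexts (the median is
order-free), but *not* to rescaling the expression values unless the
threshold is co-scaled; the suite asserts the non-invariance deliberately
since it is a property users should know.

## Testing targeted vs non-targeted components

For each enriched term and context, the log2FC values of targeted and
non-targeted term genes are compared by a Mann-Whitney U test (default) or
a two-sample Kolmogorov-Smirnov test. The package-wide orientation is that
the **targeted group is always the first sample and "less" means first
sample stochastically smaller**, so the default one-sided alternative
detects repression of targets; two-sided testing accommodates e.g.
miRNA-limited scenarios.

* MWU: exact tie-free permutation null (via the exact Wilcoxon
  distribution) when $n_x + n_y \le 20$ with no ties; otherwise normal
  approximation with tie-corrected variance and 0.5 continuity
  correction. The exact branch equals full labeling enumeration for all
  partitions with $n_x + n_y \le 10$ (asserted); the two branches agree
  within 0.01 at $n_x = n_y = 10$.
* KS: exact when $n_x n_y \le 10^4$ and tie-free, asymptotic otherwise.
  Note the direction remapping: this package's "less" (first sample
  stochastically smaller) is base R's two-sample `"greater"` (ECDF of x
  above that of y).

`minGroup = 3` per side is the testing floor — rank tests below three
observations a side carry no information; skipped terms are reported in
an attribute and a warning, never silently dropped. Genes absent from the
expression matrix are removed from both groups and counted in the row's
`direction_note`. Multiplicity is adjusted **within term across contexts**
by default, matching how the output is read (one term's context ranking
at a time); whether to adjust at all is an open design point in the
source material, so the scope is flagged in the result metadata and a
global switch exists.

# Term-centric scans

`termCentricScan()` runs the same urn transposed: for each miRNA with at
least `minTargets` targets in the universe (default 5 — tiny target sets
yield uninformative p-values; configurable down to 1), each requested term
is tested and per-term p-values are Fisher-combined per miRNA, all
p-values included for symmetry with the meta-combined default. A term the
miRNA does not touch contributes $p = 1$ here (the scan asks about the
requested terms, so every requested term is part of each miRNA's
evidence). The single-term, single-miRNA case is bit-identical to the
transposed enrichment urn (asserted).

# Screen analysis

From a MAGeCK-style `gene_summary` table (RRA pipe-separated columns
verbatim; MLE via a user column map since MLE column names depend on the
design matrix), `selectTopMirnas()` takes the top-$n$ miRNA rows of the
chosen selection direction. miRNA rows are recognized by a configurable
case-insensitive pattern (default: `hsa-`/`mmu-` prefix or `mir`
substring), since screen libraries do not flag them explicitly. Their
target union is tested for term enrichment exactly as in the main engine
(a pure delegation, asserted as identical), and each gated term is then
examined in the **opposite** ranking — for negatively selected miRNAs the
positive gene ranking — where de-repressed targets should surface.
Only gene rows are ranked: targets are genes.

* `camera`: a competitive pre-ranked test on ranks,
  $z = \frac{\bar r_m - (G+1)/2}{\sqrt{\mathrm{VIF}\,(G+1)(G-m)/(12m)}}$
  with $\mathrm{VIF} = 1 + (m-1)\rho$, referred to the standard normal.
  With $\rho = 0$ it is the Wilcoxon z-approximation (asserted within
  0.02); the default $\rho = 0.01$ is the conventional figure for
  pre-ranked competitive testing of weakly co-regulated sets.
* `fisher_topk`: one-sided hypergeometric on (top-$k$ of the opposite
  ranking) × (targeted). `kTop` is deliberately mandatory — the extreme
  size is an analysis decision, not something the package should guess.

One direction is analyzed per invocation; combining both selection
directions jointly is left to the user.

# The synthetic-data generator

`simulateData()`/`simulateFixture()` draw a complete synthetic study with
one plantable mechanism threading through all components: a designated
term whose genes the designated miRNAs target at `plantedTermFold` times
the background density (capped at 0.95), whose targeted genes are
repressed by `plantedContextShift` log2 units in one designated context,
and whose miRNA/target selection signature sits at the screen's rank
extremes. The defaults — 600 genes, 25 miRNAs, 20 terms of 25–75 genes,
background edge density 0.05, fold 4, 4 planted miRNAs, 6 contexts × 40
samples, shift 1.5, 400 screen genes, 60% of planted targets shifted by 3
latent SD — are sized like a focused custom upload (hundreds of genes,
tens of terms) rather than a genome: large enough that planted structure
is statistically recoverable with high probability, small enough that the
hundreds of replicate studies run by the test-suite calibration and
recovery checks complete in minutes on one CPU. Detection rates in
single-cell mode are uniform on 0.15–0.7 with counts of the form
Bernoulli × (1 + Poisson(2)); the context repression multiplies the
detection rate by $2^{-\text{shift}}$, which maps directly onto the
percent-expressing metric. One master seed derives one sub-stream per
component, so adding a component never perturbs the others and identical
spec + seed give byte-identical fixture files (asserted).

What the generator does **not** emulate: real annotation structure
(overlapping, nested terms), correlated expression within cell types,
miRNA co-expression, batch effects, or the scale and metadata richness of
atlas/TCGA/GTEx resources. Passing planted-recovery tests therefore shows
the machinery is wired correctly and calibrated under its own null — not
that effect sizes of this magnitude are typical of real data.

# Numerical and interface choices

* P-values are serialized with 17 significant digits in TSV and JSON, so
  a write/read round trip is bit-exact.
* Result ordering is always significance-ascending with lexicographic
  term-/miRNA-id tie-breaks, for reproducible output.
* Identifiers are opaque case-sensitive strings; no Ensembl/miRBase
  version conversion is attempted (a data-preparation concern). Ids must
  not contain commas or tabs, which serve as field separators.
* Duplicate interaction rows are collapsed at load (evidence tags
  concatenated, maximum score kept) and the collapse count reported.
* `minOverlap = 1` by default: every touched term is tested; raising the
  floor is a user decision.
* The CLI (`runCli()`, wrapped by `inst/scripts/mirtea`) maps subcommands
  1:1 onto module entry points, resolves flag > YAML config > default,
  writes a `key=value` log (version, parameters, input checksums,
  warnings) beside every result, and uses exit codes 0/2/1 for
  success/usage error/runtime error.

# Known limitations

* The Wallenius integral route is used only above $N = 2000$; its
  accuracy is cross-checked against the recursion, not against an
  external implementation.
* `camera` here is the pre-ranked, fixed-correlation variant only; no
  inter-gene correlation is estimated from expression residuals.
* The context module tests each (term, context) pair marginally;
  dependence between contexts of the same term is handled only through
  the within-term BH adjustment.
* The percent-expressing metric saturates for genes expressed in all
  samples of every context: such genes carry no context signal by
  construction.
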