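# mirTEA — miRNA-centric term enrichment and context-aware functional analysis

microRNAs repress the genes they bind, so the function of one or several
miRNAs is usually read off from the *target set* they define: which GO
terms, KEGG/Reactome pathways, MSigDB signatures or PFAM families does
that set over-represent? mirTEA is an R implementation of that analysis
engine for people who work with miRNA–target interaction tables
(experimental or predicted), GMT term collections, expression matrices
and pooled CRISPR knock-out screens — as a library and as a command-line
tool.

Four workflows are covered:

1. **miRNA-centric enrichment.** Build the union or at-least-*n*
   intersection of the query miRNAs' targets and test each term with the
   one-sided hypergeometric upper tail
   *p* = *P*(*X* ≥ *k*), *X* ~ Hypergeom(*N*, *K*, *n*),
   i.e. the one-sided Fisher's exact test of the term-membership ×
   targeted 2×2 table — or with the Wallenius non-central hypergeometric
   distribution, whose per-term odds *w* are fitted from a per-gene
   targeting-bias covariate to correct for genes that are a-priori more
   likely to land in any target set. A third design tests each miRNA
   separately and merges per-miRNA p-values per term with Fisher's method
   (χ² = −2Σ log *p*ᵢ, df = 2*k*).
2. **Context testing.** For enriched terms, compare targeted vs
   non-targeted term genes across expression contexts (cell types,
   tissues) with one-sided Mann–Whitney U (default) or
   Kolmogorov–Smirnov tests on the percent-expressing log2 fold-change
   log₂[(p_gc + ε)/(median of the other contexts' percentages + ε)],
   where a gene counts as expressed at ≥ 1 read (single-cell counts) or
   ≥ 10 TPM (tissue matrices).
3. **Term-centric scans.** Given terms of interest, rank all miRNAs by
   overrepresentation of their targets inside those terms (same urn,
   transposed; multi-term p-values Fisher-combined per miRNA).
4. **Screen analysis.** From MAGeCK-style `gene_summary` rankings, select
   the top positively/negatively selected miRNAs, test their target
   union for term enrichment, then test those targets' trend in the
   *opposite* gene ranking with a competitive pre-ranked CAMERA-style
   rank test (variance-inflation factor 1 + (m−1)ρ) or a top-*k*
   hypergeometric test.

All p-value machinery is implemented from its mathematical definition and
verified in the test suite against brute-force enumeration oracles; a
seeded synthetic-data generator with a plantable signal provides inputs
for every workflow, so no download is ever required. See
`vignettes/mirtea-methods.Rmd` for the full statistical account.

## Worked example

```r
library(mirTEA)

# a complete synthetic study: interactions, terms, expression, screen
dat <- simulateData(fixtureSpec(seed = 1))
dat$interactions
#> MirTargetSet: 769 interactions, 25 miRNAs, 440 genes
dat$terms
#> TermCollection: 20 terms (sizes 26-75), universe of 509 genes

# union target set of four miRNAs of interest
query <- dat$manifest$planted$mirna_ids
ts <- buildTargetSet(query, dat$interactions, "union")
ts
#> TargetSet (union): 142 genes from 4 miRNAs

enr <- enrichTargets(ts, dat$terms)
#> 17 target gene(s) outside the universe excluded
head(enr[, c("term_id", "genes_in_term", "targeted_in_term",
             "targets_in_universe", "p_raw", "p_adjusted")], 3)
#>    term_id genes_in_term targeted_in_term targets_in_universe        p_raw   p_adjusted
#> 1 TERM0001            70               39                 125 1.253877e-09 2.507753e-08
#> 2 TERM0003            67               22                 125 6.481558e-02 6.481558e-01
#> 3 TERM0006            66               20                 125 1.564091e-01 8.905073e-01
```

Of the 125 target genes inside the 509-gene universe, 39 fall in the
70-gene term `TERM0001` — far more than expected for a random draw of 125
genes (raw *p* ≈ 1.3 × 10⁻⁹, still 2.5 × 10⁻⁸ after BH adjustment across
the 20 tested terms), so this term is reported first. Where do its
targeted genes lose expression? Test them against the six cell-type
contexts:

```r
expr <- percentExpressingLog2fc(dat$expression$values,
                                dat$expression$sampleContexts,
                                "single_cell_counts")
ctx <- contextTest(enr[1, ], dat$terms, expr, "mwu", "less")
head(ctx[, c("term_id", "context_id", "statistic", "p_raw",
             "p_adjusted", "n_targeted", "n_nontargeted")], 3)
#>    term_id context_id statistic        p_raw   p_adjusted n_targeted n_nontargeted
#> 1 TERM0001      ctx01      16.5 1.859120e-12 1.115472e-11         39            31
#> 2 TERM0001      ctx06     604.5 5.023631e-01 9.670849e-01         39            31
#> 3 TERM0001      ctx04     652.5 7.170384e-01 9.670849e-01         39            31
```

In context `ctx01` the 39 targeted genes sit almost entirely below the 31
non-targeted term genes in percent-expressing log2FC (Mann–Whitney
U = 16.5 of a possible 1209, one-sided *p* ≈ 1.9 × 10⁻¹²): the targets are
specifically repressed there, and in no other context. (This study was
simulated with exactly that mechanism planted, so the engine recovers
what was put in.)

The statistical kernels are ordinary functions:

```r
hypergeomTest(20, 5, 10, 5)
#> hypergeom (greater): statistic = 5, p = 0.0162539 (n_x = 10, n_y = 10)
fisherCombine(c(0.5, 0.5))$p_value
#> [1] 0.5965736
```

## Command line

```sh
Rscript inst/scripts/mirtea simulate --seed 1 --outdir demo
Rscript inst/scripts/mirtea mirna-centric \
  --interactions demo/interactions.tsv --terms demo/terms.gmt \
  --mirnas hsa-miR-0001-sim,hsa-miR-0002-sim --mode union --out demo/enr.tsv
```

Subcommands `simulate`, `mirna-centric`, `term-centric`, `context` and
`screen` map 1:1 onto the library entry points; `--config file.yaml`
preloads any flag, every run writes a `key=value` log (tool version,
resolved parameters, input checksums, warnings) beside its results, and
exit codes are 0 (success), 2 (usage error), 1 (runtime error).

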