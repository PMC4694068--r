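# senescreen

Analysis of functional kinase screens that read out **cellular
senescence** by RT-qPCR. The package is written for the screen design in
which ~200 constitutively active kinases are transduced one-by-one into
normal human fibroblasts and each is scored on three axes: loss of
proliferation, induction of SASP-component transcripts (IL1A, IL1B, IL6,
IL8 — inductions can exceed 100-fold), and induction of the senescence
hallmark p16 (which moves only a few-fold). A kinase positive on all
three axes is a senescence hit.

## What it computes

1. **ΔΔCt quantification** — `normalize_ct()` averages replicate Ct
   values on the cycle scale and computes relative expression
   `2^-(Ct_gene − Ct_ACTB)`; `fold_change()` divides by the empty-vector
   control (`CTRL`), whose row is pinned to exactly 1.
2. **Staged hit calling** — `call_screen_hits()` applies the screen's
   funnel: relative proliferation ≤ 0.5, fold change ≥ 2 in ≥ 2 of the 4
   SASP genes, p16 fold change ≥ 1.5 (all configurable via
   `screen_config()`, all boundaries inclusive), then intersects the
   three calls and tallies the 7 exclusive Venn regions.
3. **Induction profiles** — `spearman_matrix()` (tie-corrected midrank
   Spearman ρ with two-sided t-approximation p-values, exact permutation
   optional for small n), `cluster_profiles()` (1 − ρ distance, average
   linkage, Newick export), `log2_matrix()` and `scale_induction()`
   (fold change 1 → 0, column max → 1).
4. **Over-representation** — `enrich()` tests a gene list against a GMT
   collection with background size N: fold enrichment `(k/L)/(K/N)`,
   log-space hypergeometric upper tail `hypergeom_upper_tail()`, the
   conservative EASE score `ease_p()` (overlap jackknifed by one gene,
   DAVID's convention) and Benjamini–Hochberg adjustment.
5. **Synthetic screens** — `generate_screen()` draws Ct/proliferation
   tables plus ground truth from a one-latent-factor model of the shared
   NF-κB program (33 planted hits among 200 kinases by default);
   `generate_genesets()` plants exact overlap geometries for testing
   enrichment. Everything is reproducible from one integer seed.

`run_pipeline()` chains stages 1–4 from TSV/GMT inputs to TSV/Newick
artifacts plus a run log; see the vignette
(`vignettes/kinase-screen-analysis.Rmd`) for the model and design
choices.

## Worked example

```r
library(senescreen)

sim <- generate_screen(synthetic_screen_spec(seed = 1))
rel <- normalize_ct(sim$ct)               # 2^-(dCt) vs ACTB
fc  <- fold_change(rel)                   # vs CTRL, control row = 1
fc  <- fc[, setdiff(colnames(fc), "ACTB")]
round(fc[c("CTRL", "KIN004", "KIN002"), ], 2)
#>         IL1A  IL1B   IL6   IL8  IKBA  SOD2  COX2  p16
#> CTRL    1.00  1.00  1.00  1.00  1.00  1.00  1.00 1.00
#> KIN004 36.08 40.53 41.67 34.77 33.99 33.83 40.45 1.45
#> KIN002  0.90  0.85  0.87  0.83  0.68  0.97  1.03 0.77
```

`KIN004` is a planted hit: every shared-program gene rises ~35-fold
while p16 rises only 1.45-fold; `KIN002` is a null. Calling hits:

```r
hits <- call_screen_hits(fc, sim$prolif)
hits
#> Kinase screen hit table: 201 kinases
#>   anti-proliferative: 33
#>   SASP inducers:      33
#>   p16 inducers:       29
#>   senescence hits:    29
```

29 of the 33 planted hits survive all three gates at this seed (the four
misses sit at the p16 boundary); no null kinase is called. Clustering
the induction profiles of the anti-proliferative kinases separates p16
from the SASP + NF-κB group on the first split:

```r
anti <- call_proliferation_hits(sim$prolif)
cluster_profiles(fc[names(anti)[anti], ])
#> Hierarchical clustering of 8 profiles ( 1 - Spearman rho , average linkage )
#> leaf order: p16 IL1B IKBA COX2 SOD2 IL8 IL1A IL6
```

Enrichment statistics from a contingency geometry (overlap 6 of an
18-gene list against a 109-gene term in a 5590-gene background):

```r
fold_enrichment(6, 18, 109, 5590)   # 17.0948
ease_p(6, 18, 109, 5590)            # 1.7997e-05
```

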