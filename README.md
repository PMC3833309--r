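# sfhscan — spatial functional hotspots from positional gene-set enrichment

Functionally related genes often sit in dense physical clusters (keratin
loci, the HLA region, interferon clusters …), so a single somatic
copy-number alteration (CNA) can hit an entire biological function at once.
`sfhscan` is for cancer-genomics analysts who want to find these loci —
**spatial functional hotspots (SFHs)** — from a gene annotation and a
functional gene-set collection, then overlay a tumor cohort's segmented
copy-number calls and survival outcomes on them.

## The method

Let *M* genes carry coordinates, tiled by sliding windows (1 Mbp wide,
0.25 Mbp step by default). Two binary indicator matrices are built:
**B** (windows × genes, row sums *x<sub>k</sub>*) and **P** (genes × sets,
column sums *y<sub>l</sub>*). Every window/set pair with positive overlap
*z<sub>k,l</sub>* is scored with the one-sided Fisher exact (upper-tail
hypergeometric) probability

P(X ≥ z) = Σ<sub>h=z</sub><sup>min(x,y)</sup> C(y,h)·C(M−y, x−h) / C(M,x),

Bonferroni-adjusted over the *T* tests actually performed. Consecutive
enriched windows for one set are merged into a run, and the run boundaries
are refined by a marginal trimming optimization: the suffix trim profile
*p<sub>R</sub>(g)* and prefix trim profile *p<sub>L</sub>(g)* are evaluated
for every position, and the refined region takes its left edge from
argmin *p<sub>R</sub>* and right edge from argmin *p<sub>L</sub>* (ties
toward the smaller region). Refined regions that stay significant are the
SFHs. Downstream, each SFH is classified per sample as gain / loss /
neutral from segmented log2 ratios (±0.2 thresholds, majority overlapped
bp), recurrence is called when strictly more than 30% of the cohort carries
the alteration, and copy-number status is screened against survival with
two-group log-rank tests (gain vs neutral and loss vs neutral) at p < 0.01.

A seed-reproducible synthetic generator (gene catalogs with planted
functional islands, GMT sets, CBS-style cohort segment calls, exponential
survival with a proportional-hazards carrier effect) makes every stage
testable without any download. See `vignettes/sfh-methods.Rmd` for the full
account of the model, parameter defaults and design choices.

## Worked example

```r
library(sfhscan)

sim <- simulate_genome(seed = 42)          # 2000 genes, 50 sets, one planted island
fit <- sfh_detect(sim$catalog, sim$sets)   # the main fitting function
fit
#> Spatial functional hotspot scan
#>   genes: 2000  sets: 50  windows: 385
#>   tests performed (Bonferroni factor): 6295
#>   enriched windows: 5  merged runs: 2
#>   hotspots at alpha 0.05: 2
#>   set_id namespace chrom    start      end n_genes  z        p_adj
#> 1    S01        CC  chr1  5020000  5270000      19 12 1.727536e-20
#> 2    S33        CC  chr2 14510787 15267922      14  6 4.178057e-03
```

The planted island (12 members of set S01 among 15 contiguous genes at
chr1:5.02–5.27 Mbp) is recovered with exactly the planted member span and
an adjusted p of 1.7 × 10⁻²⁰; the second record is a chance positional
cluster of set S33, the kind of discovery the Bonferroni level 0.05 admits.
`summary(fit)` adds per-chromosome counts and densities (hotspots/Mbp),
`plot(fit)` draws the −log10 adjusted-p landscape along the genome, and
`write_hotspots()` / `write_hotspots_bed()` export the catalog.

Overlaying a simulated 76-sample cohort in which 40% of samples gain the
island locus (log2 ≈ +0.5) and carriers have twice the baseline hazard:

```r
coh <- simulate_cohort(sim$catalog, alterations = list(
  cna_alteration("chr1", 5020000, 5270000, carrier_fraction = 0.4)),
  n_samples = 76, seed = 43)

overlay <- sfh_cna(fit, coh$segments)
#> Hotspot copy-number overlay: 2 hotspot(s) x 76 sample(s)
#>   recurrent (fraction > 0.3): gain 1, loss 0
#>          hotspot_id n_gain n_loss frac_gain frac_loss recurrent_gain ...
#> 1  S01:chr1:5020000     32      0 0.4210526         0           TRUE

survival_screen(overlay, coh$survival)
#> Survival screen: 1 log-rank contrast(s),  1 significant at p < 0.01
#>         hotspot_id        contrast n_altered n_neutral chi_square     p_value
#> 1 S01:chr1:5020000 gain_vs_neutral        32        44   9.997793 0.001567279
```

32 of 76 samples (42%) are called gain, so the hotspot is recurrent at the
30% cutoff, and the gain-vs-neutral log-rank contrast flags the survival
association (χ² = 10.0, p = 0.0016 < 0.01). `km_export()` returns the two
Kaplan–Meier step functions for plotting.

A thin command-line front end with `simulate` / `scan` / `cna` / `survival`
subcommands lives at `inst/cli/sfhscan.R`:

```sh
Rscript inst/cli/sfhscan.R simulate --seed 1 --out-dir fixtures
Rscript inst/cli/sfhscan.R scan --bed fixtures/genes.bed --gmt fixtures/sets.gmt \
    --chrom-lengths fixtures/chrom.sizes --out-prefix run
```

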