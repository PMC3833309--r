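---
title: "Detecting spatial functional hotspots: model, parameters and design choices"
author: "sfhscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spatial functional hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfhscan)
```

## The problem and the model

Functionally related genes are not scattered uniformly along chromosomes:
keratins, HLA genes, interferon genes and many other families sit in dense
physical clusters, sometimes called gene islands. When a somatic copy-number
alteration (CNA) sweeps such a locus, it perturbs an entire biological
function at once rather than a single gene. `sfhscan` finds these loci —
*spatial functional hotspots* (SFHs) — directly from a gene annotation and a
collection of functional gene sets, then asks whether each hotspot is
recurrently gained or lost in a tumor cohort and whether its copy-number
status tracks patient survival.

The detection model is positional gene-set enrichment. Let $M$ be the number
of genes in the catalog. Two binary indicator matrices are built:

* $B \in \{0,1\}^{K \times M}$ — $b_{k,i} = 1$ when gene $i$ starts inside
  sliding window $k$ (row sums $x_k$ are window gene counts);
* $P \in \{0,1\}^{M \times L}$ — $p_{i,l} = 1$ when gene $i$ belongs to
  functional set $l$ (column sums $y_l$ are set sizes).

The overlap $z_{k,l} = \sum_i b_{k,i}\,p_{i,l}$ is scored with the one-sided
Fisher exact (upper-tail hypergeometric) probability

$$
P(X \ge z) \;=\; \sum_{h=z}^{\min(x,y)}
\frac{\binom{y}{h}\binom{M-y}{x-h}}{\binom{M}{x}},
$$

the chance that a random window of $x$ genes would capture at least $z$ of
the $y$ set members. Only pairs with $z > 0$ are materialized (a zero
overlap has $p = 1$); the Bonferroni factor $T$ is the number of pairs
actually tested, and a window is *enriched* for a set when $pT < \alpha$.

Consecutive enriched windows for the same set (overlapping or abutting on
one chromosome) are merged into a run, and the run's boundaries are refined
by a marginal trimming optimization: with the run's genes indexed
$1,\dots,n$ in genomic order, the suffix profile $p_R(g)$ scores genes
$g..n$ against the full set and the prefix profile $p_L(g)$ scores genes
$1..g$; the refined region takes its left edge from $\arg\min p_R$ and its
right edge from $\arg\min p_L$. The refined region is emitted as an SFH when
its own Bonferroni-adjusted enrichment p stays below $\alpha$.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_size` | 1 000 000 | bp | Wide enough that windows carry enough genes to test (smaller windows leave many windows with fewer than ~3 genes); boundary refinement makes the final regions largely insensitive to the exact width. |
| `step` | 250 000 | bp | Quarter-window sliding, so a cluster is seen at several offsets and adjacent windows share 0.75 Mbp. |
| `min_size` (gene sets) | 15 | genes | Sets smaller than 15 members cannot reach meaningful significance against a genome background and inflate the test count. |
| `alpha` | 0.05 | — | Family-wise level for both the window scan and the refined-region call, Bonferroni-adjusted over the $T$ tested pairs. |
| `gain_thr` / `loss_thr` | +0.2 / −0.2 | log2 ratio | Conventional segmented-aCGH calling thresholds for one-copy changes against normal tissue. |
| `min_fraction` | 0.30 | — | A hotspot is *recurrently* altered when strictly more than 30% of the cohort carries the call. |
| survival `alpha` | 0.01 | — | Raw log-rank screening cutoff; the number of contrasts performed is reported so users can adjust post hoc. |

## Numerical and procedural choices

**Coordinates.** Everything internal is 0-based half-open; BED is read
as-is, GTF converted from 1-based inclusive. One unambiguous convention
beats two leaky ones.

**Tail convention.** The enrichment score is the *inclusive* upper tail
$P(X \ge z)$ — the summation starts at the observed overlap — evaluated via
`stats::phyper`, which works in log space so genome-scale $M$ neither
overflows nor loses the extreme tails. The test suite checks the
implementation against an exact combinatorial summation (and against
brute-force subset enumeration at tiny $M$) to below $10^{-10}$.

**Window membership.** A gene belongs to a window when its *start*
coordinate falls inside it. This makes membership deterministic and
overlap-free per offset; a gene straddling a window edge is owned by the
windows covering its start. A truncated terminal window is appended whenever
the stepping rule would leave a chromosome tail uncovered, and a chromosome
shorter than the window becomes one whole-chromosome window, so no gene is
ever unscannable.

**Bonferroni family.** $T$ counts the (window, set) pairs with positive
overlap — the tests actually performed. Testing the never-realizable
$z = 0$ cells would only pad the family. $T$ is reported in the fit, so the
stricter $K \times L$ family is a one-line recomputation for anyone who
prefers it.

**Run inclusion rule.** The merged run carries the union of the genes of
its windows (membership count $s_i \ge 1$). A stricter variant keeping only
genes covered by more than one enriched window (`inclusion = "strict"`) is
available; the union is the default because merging windows and then
discarding genes seen only once contradicts the purpose of merging.

**Tie-breaking and degeneracy.** Equal minima in a trim profile resolve
toward the *smaller* region — the more conservative hotspot claim. When the
two marginal argmins cross (left edge beyond right edge, which happens for
sparse membership patterns such as two isolated members at opposite ends),
the run is flagged degenerate and reported unrefined rather than silently
patched. The marginal optimization is deliberately one-pass: profiles are
computed once on the full run, exactly as the printed procedure prescribes,
and no joint two-dimensional search is attempted. One consequence, verified
by a counterexample in the test suite, is that re-applying refinement to an
already-refined span may trim further; the suite asserts the true invariant
(re-refinement never increases the enrichment p and never widens the span)
rather than idempotence.

**CNA status rule.** A hotspot's per-sample status is decided by majority
overlapped base pairs beyond the thresholds; exact positive ties are
neutral and flagged ambiguous, and hotspots with no segment coverage count
as neutral rather than missing (a conservative denominator). Both overlap
counts are always reported so any alternative rule can be recomputed.

**Survival contrasts.** Each hotspot is screened with two independent
two-group log-rank tests — gain versus neutral with loss samples excluded,
and loss versus neutral with gain samples excluded — matching the two-curve
Kaplan–Meier comparison this screen is meant to mirror, rather than a
three-group test. The log-rank statistic uses the standard pooled risk-set
formulation with the multi-death hypergeometric variance term, so tied
event times are handled conventionally; the implementation is checked
against an independent direct-summation oracle and against
`survival::survdiff`.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` plants a functional island — by default 12 members of
one set among 15 contiguous genes, spaced 20 kb so the island spans
~0.3 Mbp inside a single 1-Mbp window — on a background of 2 000 genes
placed uniformly over five 20-Mbp chromosomes (≈20 genes/Mbp, a realistic
gene density) with 50 random gene sets of 20–60 members. The planted set
has 15 members in total: 12 in the island and 3 scattered, mimicking the
island architecture in which most of a function's genes share one locus
while the set still clears the size floor. Non-members are interleaved at
the island flanks and interior so boundary refinement has genuine trimming
work. `simulate_cohort()` (default 76 samples) gives each sample the
planted alteration with its carrier probability, draws carrier segment
log2 ratios from N(0.5, 0.1) against N(0, 0.05) diploid noise in CBS-like
segments, and draws exponential survival times whose hazard is multiplied
by the hazard ratio per carried alteration, with uniform censoring
calibrated to the target censoring proportion.

The generator does **not** emulate: uneven real gene densities and gene
length distributions, the GO DAG (sets are flat and independent, whereas GO
terms nest), correlated or genome-wide arm-level CNAs, probe-level aCGH
noise, or non-proportional hazards. Passing the planted-truth tests
therefore demonstrates correctness of the machinery under idealized
conditions — it does not certify discovery performance on a real annotated
genome, where set overlap and density gradients will shift the test count
and the p-value landscape.

## Verification at the study conditions

The test suite and `scripts/acceptance.R` recompute, from scratch:

* exact-oracle agreement of the hypergeometric tail over every
  $(M \le 40, x, y, z)$ configuration (~260 000 cases);
* exact agreement of boundary refinement with exhaustive prefix/suffix trim
  evaluation on 200 random runs of up to 25 genes, plus the member-endpoint
  property;
* planted-island recovery — exactly one hotspot for the planted set whose
  gene span matches the planted member span — across 100 seeds, and
  silence of the zero-island null across 100 seeds (Bonferroni holds the
  measured per-seed false-hotspot rate near 3%, within its ≤5% guarantee;
  the occasional null hit is a genuine chance cluster of 5–7 members of one
  set among ~20 consecutive genes);
* recurrence recovery of a 40% planted gain (flagged above 0.30, not above
  0.50) across 100 seeds, run at cohort size 200 so that binomial sampling
  noise in the realized carrier fraction (sd ≈ 0.035) stays inside the
  (0.30, 0.50] corridor with probability >99.5% — at 76 samples the
  sampling noise alone would breach the corridor in roughly 5% of seeds
  regardless of implementation;
* the worked log-rank example (chi-square $= 49/17 \approx 2.882$), the
  null rejection rate at $\alpha = 0.05$ over 1 000 replicates against the
  exact binomial 99% interval, and power against a doubled hazard at
  $n = 80$ with 50% carriers and no censoring (uncensored power
  ≈ 0.7 at $\alpha = 0.01$, so a majority of seeds flag the hotspot);
* byte-identical same-seed reproduction of every written fixture and
  result file.

These problem sizes (2 000-gene genomes, 100-seed batches, 1 000 log-rank
replicates) are the package's verification conditions; each stage completes
in seconds on one core.

## Known limitations

* Boundary refinement is marginal, not joint; a two-dimensional search
  could in principle choose a different region (deliberately out of scope).
* Overlapping hotspots of *different* sets are reported as distinct — no
  cross-function deduplication is attempted, so one physical locus can
  carry many SFH records.
* Genome-wide results depend on the annotation build and the gene-set
  release; counts obtained on one annotation are not transferable to
  another.
* The survival screen is unadjusted for multiplicity by design and reports
  the number of contrasts instead; treat flagged hotspots as candidates.
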