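---
title: "Methods: scoring, testing and simulating rRNA 2'-O-methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, testing and simulating rRNA 2'-O-methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribometh)
```

## The measurement model

Ribose 2'-O-methylation protects the phosphodiester bond immediately 3' of
the modified nucleotide from alkaline hydrolysis. RiboMeth-seq reads out
this protection: RNA is fragmented at high pH, fragment ends are sequenced,
and the cleavage count at the bond 3' of nucleotide *i* is the sum of the
3'-end count at *i* and the 5'-end count at *i + 1* (`bond_end_counts()`).
A methylated site shows a dip in that count relative to its local
background.

`score_c()` turns the dip into a fractional-methylation estimate. With
flank half-width *k* (default 6) and linearly decaying weights
$\lambda_j = (k - j + 1)/k$,

$$ w_i = \frac{\sum_{j=1}^{k} \lambda_j\,(n_{i-j} + n_{i+j})}
              {2 \sum_{j=1}^{k} \lambda_j}, \qquad
   \mathrm{score}_i = \max\!\left(0,\; 1 - n_i / w_i\right). $$

The estimator assumes the background cleavage rate is *locally smooth*: the
weighted flank average stands in for the counterfactual unprotected count at
bond *i*. Under a fully efficient protection model the score estimates the
fraction of molecules methylated at the site.

Numerical contracts:

* out-of-range flank positions are dropped and the remaining weights
  renormalised, so the estimator is defined up to one bond from each end of
  the molecule and equals the plain flank value on uniform flanks at any
  window width;
* scores are clamped below at 0 (sampling noise can push $n_i$ above
  $w_i$); values above 1 cannot occur since counts are non-negative;
* a score is reported missing (`NA`, flag `low_coverage`) when the
  unweighted mean flank count is below `min_coverage` (default 10 counts):
  the score is a ratio and unstable at low depth. The threshold is
  configurable.

Site positions use local (mouse-numbering) 1-based coordinates; the
human-numbering alias carried by the catalog is display-only. The score for
a site at nucleotide *p* is computed at bond *p* (between *p* and *p + 1*).

## What the synthetic generator emulates — and what it does not

`simulate_end_counts()` draws the per-bond cleavage count as
$n_i \sim \mathrm{Poisson}\!\left(\texttt{depth} \cdot b_i \cdot
(1 - \texttt{protection} \cdot m_i)\right)$, where $m_i$ is the ground-truth
methylated fraction and $b$ a positional bias track: i.i.d. log-normal
(sd `bias_sd`, default 0.2) smoothed by a centred moving average of width
`bias_smoothness` (default 5 bonds) and normalised to median 1. Each event
is then assigned to the 3'-end track at *i* or the 5'-end track at *i + 1*
by a fair coin, modelling that a given read reports one fragment end; the
split partitions the events, so `bond_end_counts()` recovers $n_i$ exactly
and total 5' and 3' events balance up to binomial noise.

Defaults and why:

* `protection = 1`: a methylated molecule is never cleaved at the protected
  bond, which is what makes the score interpretable as "fraction
  methylated". Lower values model partial protection; the score then
  estimates `protection * m`.
* `bias_sd = 0.2`, `bias_smoothness = 5`: a background that varies by tens
  of percent but is smooth at the scale of the scoring window — the regime
  the estimator assumes. Setting `bias_sd = 0` gives a flat background for
  calibration checks.
* `depth` is the expected event count per unprotected bond; recovery
  studies here use $10^4$, where the dominant error is bias-track mismatch
  between the centre bond and its flanks, not Poisson noise.

Counts are simulated per bond directly (Poisson thinning) rather than via
explicit fragment pairs: the scorer consumes only end counts, and at the
bond level the marginal model is equivalent. The generator does **not**
emulate adapter-ligation bias, sequencing error, size-selection truncation
of the 20–40 nt fragment window, or barcode effects; passing tests
demonstrate correct recovery under the stated generative model, not
robustness to those real-data artefacts. Externally corrected count tables
can be supplied through `read_end_counts()`.

All randomness flows from one top-level seed; per-replicate and
per-molecule streams are derived with `derive_seed()`, so identical
configuration plus seed reproduces outputs byte-for-byte.

## Differential methylation

Site-level tests are Student t tests with pooled variance (`ttest_unpaired`,
df $n_1+n_2-2$) or paired on differences (`ttest_paired`, df $n-1$),
matching the two study designs (independent groups; contralateral limbs).
Welch's correction is deliberately not used. Degenerate inputs follow an
explicit contract: zero variance with equal means gives $t = 0, p = 1$;
zero variance with unequal means reports $p = 0$ with a `degenerate` flag
rather than failing.

Significance is raw $p < 0.05$ by default, mirroring the site-level
convention of RiboMeth-seq screens; a BH-adjusted mode is available
(`adjust = "BH"`). Significant sites are classified by
`classify_change()`:

* `sharp_decrease`: $\Delta \le -0.15$ RMS score,
* `slight_decrease`: $-0.15 < \Delta < 0$,
* `gain_from_nonmethylation`: $\Delta > 0$ with sham mean below
  `nonmeth_eps`,
* `increase`: remaining significant increases.

Two genuinely open choices were resolved as follows. A change of exactly
0.15 is assigned to the sharp class, the marked category in the taxonomy.
"Non-methylated in sham" has no published numeric definition;
`nonmeth_eps = 0.05` treats anything below the score's own noise floor at
high depth as absent, and is configurable.

`zscore_rows()` and `hcluster()` reproduce the heatmap preprocessing:
per-row Z-scores (zero-variance rows dropped and reported), Euclidean
distance, complete linkage by default (the metric is standard for these
heatmaps; the linkage is not published, so it is a configurable argument).
Tie-breaks in the merge sequence follow `stats::hclust()`, which is
deterministic for a given row order; permutation equivariance is covered by
tests on tie-free data.

## SNORD analysis

`find_boxes()` locates box C as the first match to `RUGAUGA` in the 5'
third (the 3' `UGA` core exact, at most one mismatch over the first four
positions, R = A/G) and box D as the 3'-most exact `CUGA` whose start lies
in the last 10 nt; internal D'/C' boxes are searched between them. The
positional windows are part of the motif definition, so the calls are
invariant to flanking padding only while the true boxes stay inside their
windows — a constraint inherent to the consensus, not an implementation
accident.

`predict_targets()` scans the antisense element (the stretch immediately 5'
of box D/D', at most 20 nt, not crossing the preceding box) against the
target for a contiguous duplex of at least `min_duplex` (default 10)
base pairs abutting the box. Watson–Crick and G·U wobble pairs are
accepted; mismatches are not, which keeps the search deterministic and
testable. The methylated nucleotide follows the fifth-nucleotide rule:
counting the first box nucleotide as position 0, the guide base at −5 pairs
with the methylated target base — equivalently the fifth target base of the
duplex window. `min_duplex < 5` is rejected because the rule needs five
paired positions.

`diff_expression()` is a deliberately simple negative-binomial Wald test,
not a re-implementation of shrinkage machinery: genes with fewer than 10
total counts are removed before testing (so the BH family size equals the
post-filter gene count), size factors are median-of-ratios with a
library-size fallback when no gene is positive in all samples, and the
per-gene dispersion is a pooled within-group method-of-moments estimate.
Two small-sample calibration choices matter at the study's replicate counts
(3 vs 4):

* the raw method-of-moments dispersion regularly undershoots (sample
  variance below the mean), which would collapse the Wald SE to Poisson
  level; each gene is therefore floored at the genome-wide median estimate
  (and at $10^{-8}$), a common-dispersion stabilisation in the spirit of
  edgeR's first estimation step;
* the Wald statistic is referenced against a t distribution with the
  residual degrees of freedom rather than the normal, acknowledging the
  noise in the plug-in SE.

With both choices, null simulations at the study design (2 000 genes,
dispersion 0.05, 3 vs 4 samples) show controlled false discovery while
planted two-fold-change genes remain detected at high sensitivity — both
properties are computed by the test suite and the acceptance script, not
asserted here. A 0.5 pseudocount on group means keeps fold changes finite
for zero-mean groups. Significance combines BH-adjusted $p < 0.05$ with
$|\log_2 \mathrm{FC}| > 1$.

`match_snords_to_sites()` joins significant methylation sites to their
annotated guides and flags concordance (site and guide moving the same
direction, guide change significant).

## Codon composition

`codon_freq()` counts codons 2..L/3 — the start codon is excluded from both
the frequencies and the GC content — and treats stop codons like any other
codon (only the start is excluded; including a terminal stop is the
simplest consistent reading). Ambiguous bases skip the transcript with a
warning. `compare_sets()` runs per-codon two-sided Wilcoxon rank-sum tests
(exact for tie-free groups of at most 8 transcripts, normal approximation
with tie correction otherwise — the groups are independent transcript sets,
so the rank-sum form applies), Bonferroni-corrected over the 64 codons,
ranked by adjusted p then absolute median difference. GC content is a
separate single test, not pooled into the Bonferroni family. The set may
overlap the background, as when comparing a pathway's transcripts against
all detected transcripts. `ora_enrich()` is the upper-tail hypergeometric
test with BH adjustment across gene sets.

`simulate_cds_set()` generates in-frame sequences as `ATG` plus i.i.d.
codons from supplied weights, so planted compositional shifts (for example
doubling the weight of `cac`) have a known answer.

## Pipeline, catalogs and problem sizes

`run_pipeline()` chains simulate → score → differential methylation →
SNORD → codon stages under one validated configuration
(`default_run_config()`, YAML via `read_run_config()`, unknown keys
rejected), writing fixed-schema TSVs, a resolved configuration copy and a
timing log. Default study conditions mirror the published design: 3
replicates per condition, baseline methylation 0.8, seven sites planted at
−0.3, SNORD counts at base mean 200 and dispersion 0.05 for 3 vs 4
samples, codon sets of 60 vs 120 transcripts of 300 codons.

The bundled 108-site catalog is a synthetic stand-in: the 30
change-reported site identifiers are as published, while the remaining 78
rows (and all local-coordinate mappings) are placeholders generated to keep
scoring windows well separated; the SNORD catalog likewise carries two
published pairings and eight synthetic ones. Analyses that need real
coordinates should supply their own catalog TSVs.

For planted-recovery studies that intersect two independent datasets, the
package uses `mini_site_catalog()` (24 sites: 7 planted, 17 null). The
reason is statistical, not computational: with per-dataset significance at
raw $p < 0.05$, the expected number of *shared* false positives across two
independent datasets grows with the null-site count ($\approx m_0 \cdot
0.05^2$), so an exact-recovery criterion is only a fair test of the
pipeline at a compact catalog. At the full catalog the same intersection
logic applies, but occasional shared false positives are an expected
property of raw-p thresholds, as reflected by decoy significant sites in
published site lists.

Problem sizes used by the test suite and acceptance script — recovery over
a six-point methylation grid at depth $10^4$ with 50 seeds per point,
10 000 null site-tests for type-I calibration, 200 random guide
constructions, 20 seeds of 2 000-gene null and 400-gene planted
differential-expression simulations, and 100 seeded codon comparisons —
were chosen so every operating characteristic is estimated with usefully
small Monte-Carlo error.

## Known limitations

* The generator's bond-level Poisson model ignores fragment-size selection
  and end-detectability effects; scores on real libraries can carry biases
  the simulation does not produce.
* Box annotation uses fixed consensus windows; genuinely non-canonical
  SNORDs (displaced boxes, long guides) will be reported as failures rather
  than rescued.
* Guide–target prediction requires a perfect (wobble-tolerant) duplex;
  single mismatches observed in some native duplexes are not modelled.
* The differential-expression test is intentionally minimal; for real count
  data with few replicates, dedicated estimators with information sharing
  across genes remain preferable.
* Site-level methylation tests use raw p-values by convention; at catalog
  scale this admits false positives by design, which the two-dataset
  intersection only partially removes.
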