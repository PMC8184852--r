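---
title: "Detecting and classifying cis-regulatory evolution of expression plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying cis-regulatory evolution of expression plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisplast)
```

## The problem

When a lineage meets a stressful environment, gene expression responds
plastically; over evolutionary time, regulatory mutations can then shift a
gene's basal expression toward (or away from) that plastic state, and can
magnify or mitigate the plastic response itself. Distinguishing these
outcomes — and deciding whether the underlying mutations act in cis (linked
to the affected allele) or in trans — requires comparing three species: an
outgroup whose stress response stands in for the ancestral plasticity, two
derived sister lineages, and F1 hybrids of each sister with the outgroup.
Inside a hybrid both parental alleles share one trans-acting environment,
so an allelic imbalance that also departs from the genomic-DNA baseline is
evidence for a cis-acting variant.

`cisplast` implements this inference chain for a stress time course
(0, 1.5, 3, 6, 12 and 24 h, four replicates): parental differential
expression, allele-specific expression against a DNA control, a
two-layer classification (basal: orthoplastic vs paraplastic; plastic:
magnified vs mitigated), parsimony assignment of cis variants to lineages,
and population-genetic summaries (pi, Tajima's D, Ka/Ks) compared across
gene groups with a gene-resampling bootstrap. A synthetic-data module
generates every input with planted truth, which is how the package
validates itself.

## The parental expression model

Counts are modelled per gene as negative binomial with a log link on the
saturated cell-means design `genotype + genotype:timepoint` and the log
median-of-ratios size factor as offset. Because the design is saturated,
the quasi-likelihood estimate of each cell rate is the ratio estimator
`sum(y) / sum(sf)`, which the package computes in closed form; the fitted
NB log cell means are the reported effect sizes everywhere:

* plasticity `s_t = log2(expr_t / expr_0)` within a species (`s_0 = 0`
  identically);
* basal difference `b = log2(derived_0 / outgroup_0)`;
* plasticity difference
  `Delta_t = log2[(derived_t / derived_0) / (outgroup_t / outgroup_0)]`.

A per-gene method-of-moments NB dispersion (with per-cell finite-sample
correction, floored at `1e-8`) and the delta-method Wald covariance are
part of the fit object.

**Significance is not taken from the plugin-dispersion Wald statistic.**
On null simulations we measured that reference to be anti-conservative at
four replicates per cell: the statistic behaves like a t with roughly half
its nominal degrees of freedom because the plugin dispersion is itself
noisy, and this excess (about 6% rejection at a nominal 5%) is enough to
distort the downstream mode classification. Contrasts are therefore tested
on the cell means of log-normalized counts with the within-cell variance
pooled across all of a gene's cells — on the log scale the within-cell
variance of NB counts is approximately constant across cells (CV^2 is
roughly `alpha + 1/mu`), so pooling is appropriate and restores the full
residual degrees of freedom (54 with 18 cells of 4). On ideal data this
construction is an exact t-test; on simulated NB data its null p-values
pass a Kolmogorov-Smirnov uniformity check. Zeros are floored at 0.5
normalized counts inside this variance machinery only; the NB fit itself
uses no pseudocounts and reported ratios always come from fitted means,
never raw count ratios.

Genes with mean count below 10 are excluded, mirroring the low-expression
filter applied to the real data this design emulates.

## The allele-specific expression model

Hybrid allele counts are aggregated per gene (the gene's allele-B fraction
is the median of per-SNP fractions, applied to the summed total and
rounded half-to-even so totals are conserved), normalized by sample-total
size factors (allele fractions are untouched), and tested with a per-gene,
per-hybrid quasi-binomial GLM (logit link) over the 7 sample types: DNA,
RNA 0 h, and RNA at the five stressed timepoints. The Pearson dispersion is
floored at 1 — the quasi-likelihood convention; allele counts are never
treated as less dispersed than binomial. The basal contrast is RNA 0 h vs
DNA; plastic contrasts are RNA t vs RNA 0 h. Testing against the DNA
baseline absorbs mapping bias: a gene whose reads misalign toward one
allele does so in DNA and RNA alike, and simulations with planted per-gene
log-odds bias up to 0.5 confirm no excess of calls.

SNP-level filters come first: SNPs within 50 bp of an intron, SNPs in
windows with more than 10 SNPs per 200 bp (divergent or misannotated
regions that map poorly) and SNPs with DNA coverage below 5 are removed,
each with a logged reason.

## Classification and thresholds

The five FDR thresholds (all Benjamini-Hochberg within gene families, one
family per test type x timepoint; boundary q equal to the threshold counts
as significant):

| layer | threshold | default |
|---|---|---|
| outgroup plasticity | `alpha_plast` | 0.05 |
| basal difference | `alpha_basal` | 0.05 |
| plasticity difference | `alpha_delta` | 0.10 |
| allelic basal | `alpha_ase_basal` | 0.05 |
| allelic plastic | `alpha_ase_plastic` | 0.10 |

A basal change is *orthoplastic* when its sign matches the outgroup's
significant plastic response at the reference timepoint (default 6 h, the
peak of the response in this design), *paraplastic* when opposite. A
plasticity change is *magnified* when `Delta` shares the sign of the
outgroup slope and *mitigated* otherwise — stated for up-regulated genes as
"positive Delta = magnification", and generalized by the sign rule so that a
derived slope of -3 against an outgroup slope of -2 is also a
magnification, while reversals land in mitigation. Crossing the two layers
yields eight modes plus `none`; `Ortho-Mit` — a basal shift toward the
plastic state combined with a damped response — is the genetic-assimilation
mode. An estimated effect of exactly zero with a significant q (a
probability-zero event in floating point) is classified `none`.

Cis/trans assignment requires concordance: *cis* needs both the parental
difference and the allelic imbalance significant with the same sign;
parental-only evidence is *trans-only*; allelic-only evidence and
discordant signs are excluded categories (the hybrid has more power than
the parental contrast, and discordance suggests compensating trans
effects). Genes with a cis signal in only one hybrid are assigned to the
corresponding derived lineage by parsimony; signals in both hybrids are
*undetermined* (they may predate the sister-species split or sit on the
outgroup branch). A gene with both basal and plastic cis signals counts as
one variant.

The quadrant test defaults to the 1-df goodness-of-fit of the ortho/para
(or magnified/mitigated) split against 1:1, `chi2 = (2k - n)^2 / n`; a 2x2
independence variant conditioning on the up/down direction is available
because the verbal description of the published analysis admits that
reading. The per-mode lineage comparison uses an 8x2 homogeneity
chi-squared (df = 7) plus a per-mode 1-df "partial" decomposition with
expectations from the lineage marginals — not a standard named test, so it
is implemented exactly as described, with an exact binomial fallback when
an expected cell drops below 1.

## The synthetic-data generator

`simulate_experiment()` is the package's ground truth. Its defaults are
the study conditions the design emulates:

* six timepoints, four replicates, mean depth 200 reads/gene/sample with
  moderate inter-gene variation (log-SD 0.35);
* NB dispersion 0.05 for totals; beta-binomial intraclass correlation 0.01
  for allele splits (the quasi-binomial test assumes overdispersion, so the
  generator plants it);
* a stress profile that ramps to its peak at 6 h and decays slowly, with
  outgroup response magnitude 1.5 log2 for plastic genes, in both
  directions (down-regulated genes get negative slopes);
* mode proportions planting ~23% of genes with a basal-change mode and
  ~15% with a plastic-change mode (none = 0.68) — the fractions of
  differentially expressed and differentially plastic genes reported in
  interspecific Arabidopsis dehydration comparisons at the peak timepoint;
  one third of unchanged genes are still (identically) stress-plastic;
* planted differences are cis with probability 0.5, decided independently
  for the basal and slope layers; origins are derived1/derived2/shared at
  0.4/0.4/0.2, with shared effects identical in both lineages;
* a per-gene, per-hybrid Gaussian mapping bias on the DNA log-odds
  (SD 0.25) shared by the RNA samples of the gene — this is what makes the
  DNA-baseline contrast necessary rather than decorative.

Seeding is counter-based: every gene derives its own substream from the
master seed, so enlarging `n_genes` never reshuffles earlier genes, and
identical seeds give byte-identical outputs.

What the generator does *not* emulate: read-level artifacts (alignment,
duplicates, positional bias), correlated gene modules, batch effects
between trials, or dispersion trends with expression level. Passing
recovery tests therefore demonstrates correctness of the inference chain
under its stated assumptions, not robustness to every failure mode of real
RNA-seq.

`simulate_population()` draws independent segregating sites from the
neutral frequency spectrum (P(i) proportional to 1/i), the regime where pi
and Watterson's theta agree in expectation, so Tajima's D is centred on
zero — a Monte-Carlo oracle for the D implementation, not a coalescent
simulator (no linkage, no tree topologies). `simulate_codon_pair()` plants
substitutions by degeneracy class (fourfold sites: any change, rate `ks`;
nondegenerate sites: rate `ka`; twofold sites: the synonymous transition at
`ks/3`, nonsynonymous transversions at `2 ka/3`, matching their 1/3 + 2/3
site accounting), so Li-style counting estimators recover the requested
rates; stop codons are never created, including by double hits within one
codon.

## Population-genetic statistics

Per-gene pi is the total mean number of pairwise differences
(`sum(ac * (n - ac)) / choose(n, 2)`), matching the "average number of
pairwise differences" convention; a per-site option exists. Tajima's D uses
the standard 1989 constants and is computed from S and pi, both
polarization-free, hence valid on folded data; S = 0 yields NA rather than
0. Ka/Ks is delegated to `seqinr::kaks()` (Li 1993 / Pamilo-Bianchi
counting with Kimura two-parameter correction — the same implementation
used in the analyses this package mirrors); its saturation sentinels
(values near 10) and negative returns are mapped to NA.

VCF filters run in a fixed order — indels, multi-allelic sites,
genotype-level depth < 10 and GQ < 20 (masked to missing), site quality
< 30, then sites with more than 80% of individuals missing — after which
every site is down-sampled (hypergeometric, seeded) to the minimum observed
allele number so spectra are comparable across sites.

The group comparison resamples genes with replacement (B = 1000 by
default), recomputes the group statistic, and doubles the smaller tail of
the bootstrap difference distribution:
`p = 2 min(#(d <= 0), #(d >= 0)) / B`, floored at `2/B` (a bootstrap cannot
claim p = 0) and capped at 1. Groups under 30 genes trigger a
high-variance warning, mirroring the exclusion of sparse modes from the
published comparison. The interspecific index `(D1 + 2) / (D2 + 2)` is
taken literally, with a warning if any D is at or below -2 (practically
impossible for Tajima's D).

## Numerical choices and degenerate inputs

* Median-of-ratios size factors need a gene expressed everywhere; absent
  that, total-count factors are used with a warning.
* Half-to-even rounding reallocates the gene-level allele split; totals are
  conserved exactly.
* A sample type with zero total excludes the gene from the ASE test with a
  reason; quasi-binomial separation (a type fixed at one allele) yields
  huge standard errors and a conservative non-call.
* Chi-squared homogeneity drops modes empty in both lineages (reducing df);
  a 2x2 with a zero cell falls back to Fisher's exact test.
* All randomness flows from explicit seeds kept below 2^31.

## Problem sizes used in validation

The test-suite and acceptance runs use 2000-gene experiments for
calibration and recovery (type-I error of the ASE layer, mode recovery,
origin assignment), 50 replicate neutral populations of 16 haplotypes and
10^4 sites for the Tajima's D check, 20 seeds of 5000 codons for Ka/Ks
consistency, 500 bootstrap null trials, and 100 simulated lineage tables
for the enrichment power check. These sizes give Monte-Carlo error
comfortably inside the asserted bounds while keeping a full run in a few
minutes on one core.

## Known limitations

* The expression and ASE layers test one reference timepoint at a time;
  multiplicity across timepoints is within-family only, as in the design
  this package follows.
* The parsimony origin rule cannot see double mutations (a variant arising
  independently in both lineages is called undetermined).
* The popgen layer assumes biallelic SNPs and free recombination between
  sites; linked-selection structure is outside the generator.
* DFE estimation from the folded spectra is deliberately out of scope.

## A worked run

```{r example, eval = FALSE}
cfg <- run_config(sim = sim_config(n_genes = 500, seed = 42), seed = 42)
bundle <- run_pipeline(cfg)
report(bundle)
```
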