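---
title: "Hemizygous X-chromosome burden testing and SNP-array mosaicism estimation"
author: "xburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemizygous X-chromosome burden testing and SNP-array mosaicism estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xburden)
```

## The scientific setting

Turner syndrome (TS) arises from partial or complete loss of the second sex
chromosome in women (45,X and related karyotypes: mosaic ring X,
isochromosome Xq, complex structural variants). Adults with TS have an
increased prevalence of diabetes/impaired glucose tolerance, obesity,
autoimmune disease, hypothyroidism, hypertension, congenital cardiovascular
anomalies (CCA) and hearing loss. Two genetic questions motivate this
package:

1. **Exome variability.** Does loss of X material perturb genome-wide
   variant load (a "ripple" effect), or does the number of variants simply
   track the amount of chromosomal material present?
2. **A two-hit hypothesis for common variants.** In monosomy X every
   X-chromosome locus is hemizygous, so a *common* population variant that
   is ordinarily buffered by a second allele is fully exposed. Do common
   hemizygous X variants act as risk or protective modifiers of the
   long-term TS phenotypes?

Around these sit two supporting analyses: candidate-gene replication on
autosomes (the TIMP3/CCA association), and SNP-array mosaicism — estimating
what fraction of blood cells carry the structural variant (ring or
isochromosome) line from B-allele frequencies (BAF) and log R ratios (LRR).

The cohort structure the package targets is seven groups: 45,X monosomy
(n = 75), mosaic ring X (20), complex (5), isochromosome Xq (34), 46,XX
controls (23), 46,XX primary ovarian insufficiency (101) and 46,XY controls
(11). Raw human data of this kind are access-restricted, so the package
ships a synthetic-cohort generator with this structure as its default; every
analysis stage is exercised end to end on generated data.

## The burden model

For one clinical condition, the monosomy-X analysis set splits into samples
*with* the condition ($n_1$) and *without* it ($n_2$); samples with unknown
status are excluded, never imputed. The default with/without sizes in the
generator mirror the study groups: diabetes 25/24, obesity 19/53,
autoimmunity 24/28, hypothyroidism 32/43, hypertension 16/36, CCA 17/35,
hearing loss 14/33 (remainder unknown).

Variants are first restricted to *common* ones, population allele frequency
in $[0.1, 0.9]$ (inclusive; records with missing frequency are dropped and
counted). Only around a mid-range frequency can carrier proportions differ
substantially in either direction — the window is matched to the effect
size screened for. Carriers are then collapsed per **gene** (unique
individuals with at least one qualifying variant in the gene) or per
**variant**, giving a 2×2 table per unit:

|              | carriers | non-carriers |
|--------------|----------|--------------|
| with         | $a$      | $b$          |
| without      | $c$      | $d$          |

with $a + b = n_1$ and $c + d = n_2$: genotyped samples with zero qualifying
variants still contribute to denominators. Per unit the package reports:

* **effect size** $\Delta = a/n_1 - c/n_2$, flagged *risk* when
  $\Delta > 0.35$ strictly and *protective* when $\Delta < -0.35$;
* the **two-sided Fisher exact p** under the point-probability rule: the
  sum of hypergeometric point probabilities (conditional on both margins)
  of tables no more probable than the one observed, compared with relative
  tolerance $1 + 10^{-7}$ — the convention of mainstream statistical
  environments, stated explicitly because mid-p or tail-doubling rules give
  different values;
* the **conditional maximum-likelihood odds ratio**: the $\psi$ solving
  $E_\psi[A] = a$ under the noncentral hypergeometric distribution, with an
  exact 95% interval from inverting one-sided tests at 2.5% per side;
  boundary tables give 0 or $\infty$ with a one-sided interval. The odds
  ratio is always oriented carriers-with versus carriers-without, so its
  sign agrees with $\Delta$ (published tables occasionally flip the
  orientation for individual rows; this package never does);
* the **Bonferroni-adjusted p**, $\min(1, m\,p)$, where $m$ is the number
  of units with qualifying data for that condition — the stringent choice
  of correcting over every gene on the X chromosome with data (>600 in
  practice). The exact $m$ depends on the data, so adjusted p-values are
  reported but not treated as externally comparable constants.

`run_burden()` wires these together and returns a `burden_scan` object
(sorted by $|\Delta|$) with `print`, `summary` and `plot` methods:

```{r burden-example, eval = FALSE}
co  <- simulate_cohort(simulation_config(seed = 1))
std <- standard_filter(co)
scan <- run_burden(std, "hypertension", level = "gene")
summary(scan)
plot(scan)
```

The same machinery runs the extended pseudoautosomal (PAR) analysis:
restrict to `par_regions()` (PAR1 X:10,001–2,781,479, PAR2
X:155,701,383–156,030,895, GRCh38, shipped as an editable constant) and
widen `karyotypes` to all TS groups, since PAR genes are haploinsufficient
in all of them. In that multi-karyotype set heterozygous and homozygous alt
genotypes both count as carrier, which is what the any-record rule already
implements.

## Variant filtering

Two pipelines run in parallel on the merged cohort:

* **somatic-mosaic**: depth ≥ 40 reads and VAF in $[0.05, 0.25]$, both VAF
  bounds inclusive ("between ... and" read inclusively, "at least"
  likewise). The window balances sensitivity against read-sampling noise
  below 5% and genuine heterozygous calls above 25%. An optional quality
  floor exists but defaults to off.
* **standard** (germline/early-somatic): quality, depth and VAF floors that
  are entirely configuration-driven. The shipped defaults (quality ≥ 20,
  depth ≥ 10, VAF ≥ 0.25) are conservative placeholders: no canonical
  published criteria exist for this stage, so the configuration *is* the
  contract, and tests exercise behaviour across configurations rather than
  one blessed threshold set.

Both filters are idempotent and monotone in every threshold (tested as
properties), and with the default VAF floor the two outputs can only
overlap at VAF exactly 0.25.

## Exome variability

`count_by_consequence()` produces one count vector per (sample, chromosome
class), classes autosomal (1–22) and X; Y and mitochondrial records are
excluded and tallied separately. Counts split by predicted translational
impact (missense, synonymous, frameshift, in-frame, stop-gain, other); the
annotation-string mapping is total, with unmapped strings counted and
classed *other*. Group comparison uses the Kruskal–Wallis rank test
(midranks, standard tie correction; degenerate all-equal input returns
p = 1), with per-group medians and quartiles for box-plot style reporting.
Pairwise post-hoc contrasts are Dunn-style rank comparisons with Bonferroni
correction — a design choice made here, since no canonical post-hoc method
is attached to this analysis.

## Candidate-gene replication

`candidate_allele_counts()` compares alternate-allele frequencies of common
variants in one autosomal gene between phenotype groups: het contributes 1
allele, hom-alt 2, and each participating individual contributes 2 to the
denominator; individuals with a record but unknown genotype class are
excluded from both totals at that variant. "MAF" here means the tabulated
alt-allele frequency without minor-allele folding (published comparisons
tabulate frequencies above 0.5). The Fisher p on the allele table is
invariant to which allele is labelled minor. Allele counts rather than
carrier counts reproduce the published TIMP3 fractions (6/44 vs 5/146),
which is why that convention was chosen.

## SNP-array mosaicism

A two-population copy-number mixture with line-2 fraction $f$ predicts

$$\mathrm{E[BAF]} = \frac{(1-f)a_1 + f a_2}{(1-f)c_1 + f c_2},
  \qquad \mathrm{E[LRR]} = \log_2 \frac{(1-f)c_1 + f c_2}{2}.$$

Presets: **ring** (45,X line vs 46,X,r(X): 1 vs 2 copies, informative
marker $(a_1, a_2) = (0, 1)$) and **isoXq** (45,X vs 46,X,i(Xq) on the q
arm: 1 vs 3 copies, the isochromosome carrying two identical q-arm alleles,
$(a_1, a_2) = (0, 2)$).

BAF estimation excludes homozygous markers (BAF outside $(0.05, 0.95)$;
thresholds configurable), folds the rest about 0.5 (band positions are
symmetric under allele relabelling), and takes the band position $b$ as a
robust folded median: a first-pass median followed by a second pass that
drops points further than $\max(3\,\mathrm{MAD}, 0.05)$ from the centre.
The two-pass rule exists because homozygous markers whose noise leaks past
the exclusion threshold otherwise bias the band median; the reported
residual is the MAD of the retained band members. Inverting the mixture
formula gives $f$ — for the ring shape $f = b/(1-b)$. For shapes whose band
can cross 0.5 (isochromosome), folding leaves two candidate solutions; the
one whose expected LRR best matches the observed median LRR is chosen.
Bands within 0.01 of the exclusion threshold are indistinguishable from
homozygous noise: the estimate is then 0 with a `"no heterozygous band"`
flag — the practical detection limit of the band method, which is why the
`combined` method falls back to the LRR estimator
($f = (2^{\tilde{L}+1} - c_1)/(c_2 - c_1)$, clamped to $[0,1]$) when no
band is found but the intensity clearly departs from one copy. Estimation
requires at least 30 markers (configurable); under the simulated noise
model (truncated Gaussian BAF noise, SD 0.03; LRR noise SD 0.15; 500
markers) the BAF estimator recovers $f \in \{0.1, \dots, 0.9\}$ within
±0.03 and the LRR estimator within ±0.05, checked in the test suite.

Original-versus-array mosaicism comparisons use the Wilcoxon matched-pairs
signed-rank test (`paired_signed_rank()`): zero differences dropped, exact
null distribution up to 25 non-zero untied pairs, normal approximation with
tie handling above.

## Power

`power_two_proportion()` gives the normal-approximation power of the
two-sided two-proportion test (pooled variance under the null, unpooled
under the alternative); at $\Delta = 0$ the power equals $\alpha$ exactly.
It justifies the $|\Delta| > 0.35$ screen: at the diabetes group sizes
(25 vs 24) and a baseline carrier proportion of 0.3, power at
$\Delta = 0.35$ is about 0.70. The analytic form is cross-checked in the
tests against a 50,000-replicate Monte-Carlo using the exact Fisher test;
they agree within a few percentage points at these sizes — adequate, since
the screen is a coarse triage threshold, not an inferential boundary.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, and its defaults *are* the
study conditions: the seven group sizes above, the per-condition
with/without counts (assigned exactly in the monosomy group and scaled
proportionally in the other TS groups; controls carry no phenotype labels),
650 X-chromosome genes with variant data of which 25 are pseudoautosomal,
300 autosomal genes, 2 common variants per gene, and population allele
frequencies uniform on $(0.05, 0.95)$ so the 0.1–0.9 window filter is
exercised on both sides.

Carrier status per variant and sample is Bernoulli with probability
$1 - (1 - \mathrm{af})^{x_c}$, where $x_c$ is the group's X-copy
equivalent (45,X and 46,XY 1; ring 1.3; complex 1.5; isochromosome 1.7;
46,XX and POI 2; autosomal loci use 2 with het/hom split by
Hardy–Weinberg). This makes per-sample X-variant totals proportional to the
amount of X material, the qualitative signature the variability analysis
expects, with the fractional exponents standing in for partially retained or
mosaic X material. Planted effects `(gene, condition, delta)` shift the
planted variant's carrier probability by `delta` in with-condition samples;
the generator forces that variant's baseline frequency into a feasible
mid-window range and rejects infeasible deltas outright. Read depth is
negative-binomial (mean 60, size 6), putting real mass on both sides of the
40× somatic threshold; germline VAFs sit near 1 (hemizygous/hom) or 0.5
(het), and a configurable 8% of records instead draw VAF in $(0, 0.3)$ to
emulate somatic-mosaic events. Call qualities are gamma (mean 50, SD 12.5):
common germline calls at this depth are high-confidence, so almost all pass
the standard filter's default quality floor. A single seed makes the whole
cohort byte-reproducible.

What the generator does **not** emulate: linkage disequilibrium, a
realistic site-frequency spectrum, sequence context, batch effects, or any
correlation between phenotypes. Passing tests therefore demonstrate that
the *pipeline machinery* is correct under the stated statistical structure,
not that real cohorts behave this way.

One consequence is worth stating plainly. With ~650 independent genes and
group sizes 16/36, the largest null $|\Delta|$ has expectation around 0.4
(per-gene SD of $\Delta$ is ~0.13–0.15 for mid-range frequencies), so a
planted $\Delta = 0.45$ gene is the single top hit in only roughly half of
simulated cohorts — whole-cohort top-1 recovery at these group sizes is
intrinsically hard under a uniform frequency spectrum, and the package
reports the measured rate honestly rather than adjusting the conditions
until recovery looks comfortable. The companion family-wise error check
(any Bonferroni-significant gene under the null in ≤ 8% of cohorts) passes
with a wide margin, as expected for the doubly conservative
Fisher-plus-Bonferroni combination.

## Numerical and degenerate-input choices

* 2×2 tables with a zero row or column margin are uninformative: p = 1, and
  the odds ratio is reported as undefined.
* The conditional-MLE score equation is solved on the log-odds scale by
  bisection to tolerance $10^{-10}$; tests require agreement with direct
  likelihood maximisation to $10^{-6}$ relative and with full hypergeometric
  enumeration of the p-value to $10^{-12}$.
* Merging deduplicates on (sample, chrom, pos, ref, alt) keeping the
  higher call quality; equal-quality ties keep the first by input order and
  are logged. The merged table is canonically sorted, so merging is
  order-independent.
* Coordinates are 1-based fully closed (VCF convention, GRCh38 labels);
  `chr` prefixes are stripped. VAF precedence in VCF input: an explicit
  per-allele `AF` FORMAT field wins, otherwise `AD`-derived
  ($AD_{alt}/\sum AD$); records with neither are skipped and counted.
* All-identical input to the rank test returns p = 1 (degenerate), as does
  an all-zero-difference paired comparison.

## Problem sizes used in the checks

The simulation studies in the test suite and acceptance script use: 200
seeds for planted-signal recovery and for the null family-wise rate
(monosomy-only cohorts, 650 X genes, one variant per gene), 1,000
replicates for the Kruskal–Wallis size check, 500 markers per simulated
array profile across $f = 0.1, \dots, 0.9$, and 50,000 Monte-Carlo
replicates for the power cross-check. These sizes give Monte-Carlo
standard errors comfortably below the tolerances being asserted.

## Limitations

* The standard-filter criteria and the exact Bonferroni denominator used in
  any particular published analysis are not recoverable from public
  sources; both are explicit configuration here.
* Absolute variant totals from the original study (millions of autosomal
  variants) depend on unavailable raw sequencing data and are out of scope;
  only statistics derivable from printed tables are reproduced.
* The mosaicism estimator assumes exactly two cell lines; three-line
  mixtures (e.g. 45,X / 46,X,i(Xq) / 46,XX) would need a larger model.
* Burden testing uses no covariates, no kinship correction and no logistic
  modelling — deliberately matching the analysis it reimplements.
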