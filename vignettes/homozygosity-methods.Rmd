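---
title: "Genome-wide homozygosity and disease risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide homozygosity and disease risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohburden)
```

`rohburden` implements a complete case-control analysis of genome-wide
homozygosity burden: runs-of-homozygosity (ROH) detection from hard-call SNP
genotypes, the FROH and F3 inbreeding summaries, covariate-adjusted logistic
association per study, a regional 500-kb bin scan, and cross-study
meta-analysis. This vignette explains the model, its assumptions, the tunable
parameters, and the design decisions that were genuinely open.

## The ROH caller

Autozygosity — both chromosome copies descending from a recent common
ancestor — shows up on genotyping arrays as megabase-scale runs of homozygous
calls. The caller is a two-step sliding-window procedure over each sample and
chromosome:

1. **Flagging.** Every contiguous window of `window_snps = 50` SNP indices
   that lies fully inside the chromosome is classified as *homozygous* iff it
   contains at most `window_max_het = 1` heterozygous and
   `window_max_missing = 5` missing calls (absorbing a small amount of
   genotyping error and dropout). A SNP is flagged when the fraction of
   homozygous windows among the windows covering it is at least
   `hit_threshold = 0.05`.
2. **Run building.** Maximal stretches of flagged SNPs become candidate runs.
   A run is split wherever the gap between adjacent member SNPs exceeds
   `max_gap_kb = 5000`, its ends are trimmed inward to the nearest
   non-missing homozygous genotype (so segments start and end on evidence),
   and survivors must hold `min_snps = 100` SNPs, span `min_kb = 1500` kb and
   average at most `density_kb_per_snp = 50` kb per SNP.

These defaults are the standard "1.5 Mb" calling configuration for detecting
recent autozygosity on SNP arrays; all eight values are exposed in
`roh_params()`.

Two edge policies were open and are fixed as follows. Near chromosome ends a
SNP is covered by fewer than 50 windows; the hit ratio uses the number of
*existing* windows as its denominator so edge SNPs remain reachable, and a
chromosome shorter than one window is evaluated as a single truncated window.
Second, heterozygotes are capped per *window* only: runs are built purely from
window-derived flags with no extra run-level heterozygote cap. A consequence
of the 5% hit threshold is that the outermost one or two SNPs of a homozygous
block adjacent to heterozygous flanks fall below the ratio and are not
flagged, so called segments shave a couple of SNP spacings off each tract
end; at array densities this is far below the kb granularity of every
threshold.

The segment-length convention is `end_bp − start_bp + 1` with 1-based
inclusive coordinates (the map-file convention); alternative conventions
differ by a few bp, below any threshold's granularity.

## Burden summaries: FROH and F3

**FROH** is the fraction of the autosome covered by called ROH:
segment lengths summed and divided by a fixed 3×10⁹ bp. The denominator
deliberately stays 3×10⁹ when chromosomes are excluded in sensitivity
analyses, so that log-odds per unit FROH remain comparable across runs; a
`renormalize` flag provides the alternative.

**F3** estimates the correlation between uniting gametes from the genotypes
directly. With genotype $x \in \{0,1,2\}$ counting copies of the
frequency-$p$ allele, the per-SNP term is

$$\frac{x^2 - (1+2p)\,x + 2p^2}{2p(1-p)},$$

averaged over non-missing SNPs with $0 < p < 1$. Heterozygotes contribute
exactly $-1$ at any frequency; the homozygotes contribute $p/(1-p)$ and
$(1-p)/p$, so the term has expectation zero under Hardy–Weinberg equilibrium.
Outbred samples therefore sit near zero (often slightly negative), autozygous
samples are positive. Allele frequencies are estimated per study from all
non-missing calls (cases and controls together), mirroring per-study
analysis; monomorphic residues are skipped.

Note a scale subtlety at desk scale: F3 is an average over the *typed* SNPs,
so on a simulated genome of 120 Mb a sample with 12% of that genome in
tracts has F3 ≈ 0.12, while its FROH (fixed 3×10⁹ denominator) is ≈ 0.005.
On a genome-wide map the two scales coincide; comparisons of the two
coefficients should keep this in mind for toy genomes.

## Quality control

Pre-analysis filters follow standard GWAS practice and are applied in a
fixed order so drop reports are reproducible: minor allele frequency < 0.05
(all samples, non-missing calls), then per-variant missingness > 3%, then
Hardy–Weinberg exact p < 10⁻⁶ among controls; finally samples with call rate
< 97% are removed and each survivor's missing-call fraction is recorded as a
covariate. The HWE test is the plain two-sided exact test (no mid-p),
conditioning on allele totals and summing probabilities of heterozygote
counts no more probable than the observed one — the de-facto standard for
genotype QC. MAF is computed over all samples because the control-only
restriction applies, explicitly, only to the HWE filter.

## Association models

Per study, case-control status is regressed on the burden metric (or on a
bin's exposure indicator) by logistic regression via iteratively reweighted
least squares (`glm`, log-likelihood tolerance 10⁻⁸, 50 iterations), with
Wald standard errors. The default covariate set is age, sex and
missing-call fraction, plus any requested number of ancestry principal
components. Constant covariate columns are dropped with a warning — this is
what makes a single-sex study (where the sex column is uninformative) run
unmodified. Separation and non-convergence are reported via a `converged`
flag rather than an error.

The interpretation anchor: the coefficient is the log-odds per *unit* FROH,
so `exp(0.001 * beta) − 1` is the relative risk increase per 0.1% of the
autosome in ROH.

PCs are computed on genotypes standardised to mean $2p$ and variance
$2p(1-p)$, with missing calls mean-imputed for this step only, no LD
pruning (an option at desk scale, where maps are LD-free by construction),
scores scaled to unit variance, and each component's sign fixed by a
positive loading sum so repeated runs are identical.

**Bin scan.** Each autosome is tiled from position 1 with half-open 500-kb
bins out to its last mapped SNP. Each called segment contributes its
midpoint, `floor((start + end)/2)`, to exactly one bin; a sample is exposed
at a bin iff at least one of its segments' midpoints lands there (an
indicator, not a count). Bins with fewer than `min_exposed = 5` exposed
samples, or with all exposure in one arm (guaranteed separation), are
reported as skipped with a reason instead of fitted — the sparse-bin policy
is a declared choice of this package, since reasonable alternatives
(dropping silently, Firth correction) exist.

## Meta-analysis

Study estimates are combined two ways, matching the two tool conventions the
field uses: DerSimonian–Laird random effects for the burden metrics and
inverse-variance fixed effects for the bin scan (overridable for either).
With weights $w_i = 1/se_i^2$,

$$Q = \sum w_i(\beta_i - \beta_{FE})^2,\qquad
\tau^2 = \max\!\left(0, \frac{Q - (k-1)}{\sum w - \sum w^2 / \sum w}\right),\qquad
I^2 = \max\!\left(0, \frac{Q-(k-1)}{Q}\right)\cdot 100,$$

and the random-effects combination re-weights by $1/(se_i^2 + \tau^2)$. The
heterogeneity p-value is the upper tail of $\chi^2_{k-1}$ at $Q$. No
continuity or Hartung–Knapp adjustment is applied. Whenever $Q \le k-1$ the
random-effects result reduces exactly to fixed effects. Leave-one-out
re-analysis traces heterogeneity to single outlying studies, and Bonferroni
control divides $\alpha$ by the literal number of combined tests.

## The synthetic-cohort generator

Real multi-study genotype panels are not redistributable, so validation runs
on synthetic cohorts with exact ground truth. Autozygosity is modelled by
*explicit tract planting* rather than pedigree or coalescent simulation:
recovery tests need per-sample truth, and pedigree realism is a non-goal.
Per sample, a Poisson(λ = 6) number of tracts with lengths 1600 kb +
Exponential(mean 900 kb) is placed uniformly without overlap; inside a tract
genotypes are homozygous with the allele chosen by its frequency, outside
they are Hardy–Weinberg draws at Uniform(0.05, 0.5) frequencies. Each call
is flipped to a heterozygote with probability 0.002 (kept below the
one-het-per-50-SNP window allowance so planted tracts stay callable) and set
missing with probability 0.002 so the missing-fraction covariate is
estimable. Mild substructure comes from two Balding–Nichols subpopulations
at divergence 0.005. Disease status follows
$\text{logit}\,P(\text{case}) = \alpha + \beta_{FROH}\cdot FROH_{true} +
\beta_{age}(age-\bar a) + \beta_{sex}\cdot male$ (default
$\beta_{FROH} = 20$), sampled retrospectively to exact case/control quotas —
the design of case-control studies, under which the logistic slope is
preserved. An optional regional risk bin plants an extra tract covering a
chosen 500-kb bin with given probability and adds its log-OR to the model; a
single-sex option draws controls from females only.

The default genome is desk-scale: two 60-Mb chromosomes with 12,000 SNPs
(~10 kb spacing, enough that a minimum-length tract holds well over the
100-SNP calling floor). Under these defaults the median simulated FROH is
≈ 0.45–0.5%, inside the 0.38–0.77% band that genome-wide array studies of
European-ancestry cohorts report — note FROH keeps the full 3×10⁹
denominator, so desk-scale values are directly on the reported scale. What
the generator does **not** emulate: linkage disequilibrium (SNPs are
independent given the tract structure), allele-frequency spectra beyond the
uniform band, short ancient ROH below the 1500-kb calling floor, and somatic
artefacts. Passing recovery tests therefore demonstrates correctness of the
pipeline's inference under its stated model, not robustness to every
property of real array data.

All randomness flows from one integer seed; per-stage seeds are derived from
it, every simulated object records the seed, and reruns are bit-identical.

## Validation scales and numerical choices

The test-suite problem sizes are chosen to exercise each property at the
smallest scale where it is informative: oracle equivalences (HWE enumeration
to totals of 50, F3 brute force on 100×1000, the closed-form 2×2 logistic
fit, hand-computed meta-analysis examples) are exact to 10⁻¹² or 10⁻⁶;
caller sensitivity and false-positive checks use clean cohorts of 120
samples and null genomes of 50 × 20,000 SNPs over 20 seeds; parameter
recovery runs 100 studies of 2,000 cases and 2,000 controls at true
$\beta_{FROH} = 20$ and asks for 2-SE coverage in at least 93; the type-I
error of the burden test uses 500 phenotype redraws at $\beta = 0$ on a
reduced cohort, judged against a 99% binomial band around 0.05.

The large recovery loop simulates cohorts without substructure and adjusts
for age, sex and missing fraction but not PCs: tracts are planted
independently of subpopulation, so PCs are pure noise covariates there, and
the loop's job is coverage of $\hat\beta$, not stratification control. PC
behaviour (separation of planted subpopulations, determinism, rank
handling) is validated separately.

Degenerate inputs are handled explicitly rather than by accident:
monomorphic variants give HWE p = 1 and are skipped by F3; a cohort with no
controls must disable the HWE filter explicitly; zero-variance exposures and
single-class outcomes are errors; an empty segment set yields FROH 0; and
excluding every chromosome leaves F3 undefined (`NA`) rather than raising.

## Known limitations

- The caller is the window heuristic, not an HMM or LOD-based method;
  short/ancient homozygosity below 1500 kb is invisible by design.
- F3 inherits sensitivity to allele-frequency misspecification and to
  population substructure; per-study frequency estimation mitigates but does
  not remove this.
- The bin scan tests marginal exposure bin-by-bin; no conditional or
  haplotype modelling.
- Synthetic cohorts are LD-free; QC filters are exercised on planted
  violations rather than realistic failure modes.
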