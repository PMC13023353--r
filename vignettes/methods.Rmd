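---
title: "SexLinkScan: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SexLinkScan: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

SexLinkScan infers whether a gonochoric species is male-heterogametic
(XX/XY) or female-heterogametic (ZW/ZZ) from population genotypes and sex
phenotypes, and screens insertion/deletion polymorphisms for use as
PCR-resolvable sexing markers. This vignette is the package's own account
of the science: the statistical model at each stage, the simulator that
the test suite relies on, the numerical conventions, and the places where
the design was genuinely open and a choice had to be made.

```{r setup}
library(SexLinkScan)
```

## The inference problem

At a fully sex-linked locus the heterogametic sex carries one copy of a
sex-chromosome-specific allele and is therefore heterozygous, while the
homogametic sex is homozygous. Under XX/XY that means males heterozygous
and females homozygous; under ZW/ZZ the mirror image. Three signatures
follow, and the pipeline checks all three:

* **association**: allele dosage predicts sex genome-wide only near the
  sex-determining region (SDR);
* **zygosity segregation**: at the significant loci, heterozygosity is
  concentrated in one sex;
* **diagnostics**: a length-polymorphic variant in the region yields one
  gel band in the homogametic sex and two in the heterogametic sex.

Real data are noisy — genotyping error, missing calls, incomplete linkage
between markers and the SDR — so none of the proportions is exactly 1, and
every decision rule below has an explicit threshold.

## Stage-by-stage model

### Filtering

Hard filters apply the conventional caller thresholds per variant type
(strict inequalities; an absent annotation never fails a site, matching
the upstream caller's behaviour when an annotation is undefined). Site
filters retain biallelic sites with minor allele frequency ≥ 0.05
(computed over non-missing calls only), mean depth ≥ 3 and missing
fraction ≤ 0.25 — the last being the VCFtools `max-missing 0.75`
convention (≥ 75% of samples called) restated as a missingness bound.
Half-missing genotypes (`./1`) are treated as missing, which is the
conservative reading. Multi-allelic sites are dropped rather than split,
consistent with a biallelic downstream model. Filtering is idempotent and
order-preserving.

### PCA covariates and the eigenvalue > 1 rule

Missing dosages are mean-imputed per site, sites are centred and scaled to
unit variance, and the eigenvalues reported are those of $(1/p)XX^{\top}$
for the standardised $n \times p$ matrix $X$. On this scale the
eigenvalues sum to $n-1$ and average 1 over the non-null spectrum, so the
Kaiser-style "eigenvalue > 1" covariate rule selects components that
explain more than the average standardised variance. This scale choice is
deliberate: on the naive covariance scale with $p \gg n$ every non-null
eigenvalue is of order $p/n$ and the rule would select everything. Score
signs are fixed by orienting each component so its largest-magnitude
loading is positive, making results reproducible across linear-algebra
backends. By default `min(20, n-1)` components are computed.

### Association scan

The scan regresses the 0/1 sex phenotype (female = 0, male = 1 — the
package-wide coding) on intercept, PC covariates and dosage by ordinary
least squares, testing the dosage coefficient with a two-sided t test.
A linear model on a binary phenotype mirrors the GLM of the classical
GWAS toolkits this stage emulates; since the t test on β is equivalent to
the score test for association under the null, its type-I error is
correct, which the test suite verifies on null simulations (fraction of
p < 0.05 within Monte-Carlo error of 0.05 at 10,000 sites, λ within
[0.9, 1.1]).

Numerical conventions: samples missing a dosage are dropped for that site
only; monomorphic or covariate-collinear sites are returned untested
rather than erroring; p-values are clipped below at 1e-300 so −log10
transforms stay finite; and when the matrix has no missing calls at all
the scan is computed by residualising once against the covariate block
(Frisch–Waugh), which is algebraically identical to the per-site fit —
the suite asserts agreement of the two paths to 1e-10.

λ is the median of the χ²₁ quantiles implied by the p-values divided by
0.4549364 (the χ²₁ median). The significance modes are Bonferroni
(p < α/N), suggestive (p < 1/N) and fixed, all strict. The suggestive
default of 1/N is a convention, not an estimate; any published analysis
using a different cutoff can be reproduced with `mode = "fixed"`.

### LD decay, sufficiency and windows

r² is the squared Pearson correlation of dosages over samples non-missing
at both sites (composite LD) — the natural choice for unphased genotype
data. The decay curve bins all intra-chromosomal pairs up to `maxDist`
(default 300 kb) into `binSize` bins (default 100 bp) and takes raw means;
no smoothing is applied, so the half-decay distance — the midpoint of the
first bin whose mean r² is at or below half the maximum (≤ with a 1e-12
float tolerance, so an exact half counts) — is deterministic. The
marker-sufficiency bound `round(G/d)` says how many evenly spaced markers
a genome of size G needs for every point to sit within the informative LD
range of some marker.

Significant variants cluster greedily (gap < `minGap`, default = flank,
so clusters merge exactly when their windows would overlap); the lead is
the lowest p with ties broken leftmost; windows are lead ± flank clamped
to [1, chromosome length]. The flank defaults to the computed half-decay
distance and can be fixed to any value (e.g. 5844 bp) to match an
external analysis. Gene assignment is inclusive interval overlap (≥ 1 bp)
via GenomicRanges.

### Zygosity pooling and the system call

The segregation summary pools **calls**, not loci: every non-missing
genotype at every significant locus contributes once, so a zero-missing
matrix of 571 loci × 287 individuals yields exactly 163,877 calls.
Missing calls leave all denominators. Dosage-2 individuals of the
heterogametic sex count as homozygous evidence *against* the expected
system — no special-casing. The call requires both pooled proportions of
one orientation to reach their thresholds (`tHet`, `tHom`, default 0.7);
with thresholds above 0.5 the XY and ZW rules are mutually exclusive, and
anything else is `undetermined`. The default 0.7 sits well above the
autosomal expectation of about 0.5 yet tolerates several percent
genotyping error; the suite shows p(het|male) decreasing monotonically in
the error rate and 100/100 correct XY/ZW recoveries at 5% error.

### InDel markers and band prediction

Candidates need an allele length difference strictly greater than 8 bp
("longer than 8 bp" read as ≥ 9 — the scale a short agarose run resolves)
and a segregation pattern where the heterogametic sex is heterozygous and
the homogametic sex homozygous for its modal allele, at concordance ≥
`minConcordance`. Scoring the homogametic sex against its *modal*
homozygous dosage makes the screen orientation-agnostic (the sex-linked
allele may be REF or ALT in the VCF). Ranking is concordance, then length
difference, then position — deterministic under reordering; how a wet lab
would rank sixty candidates before PCR testing is genuinely
under-determined, and this rule simply prefers the most diagnostic, most
resolvable markers first. Band prediction is arithmetic: heterozygotes
show the reference amplicon plus the amplicon ± the InDel length;
`resolvable` flags differences ≥ 8 bp on amplicons ≤ 500 bp and is a
reporting aid, not a physical gel model.

### Expression stage

The DE test is a deliberate simplification and documented as such:
library normalisation by total counts (scaled to the mean library size),
fold change `log2((mean_testis + 1)/(mean_ovary + 1))` with pseudocount 1
for zeros, and a Welch t test on `log2(norm + 1)`. It is not a
negative-binomial shrinkage model; with three samples per group its power
is modest, and the acceptance properties are therefore defined on
synthetic truth recovery (recall ≥ 0.9 for |log2FC| = 4, dispersion 0.1),
never on equality with any published DE tool. DEG thresholds are strict
(|log2FC| > 1 and p < 0.05 on raw p-values; a BH-FDR option exists but is
off by default, matching the raw-p convention of the analyses this stage
mirrors). 2^−ΔΔCt is the standard qPCR quantity and is invariant to
adding a constant to all four Ct values. The GWAS × DEG overlap is an
exact id intersection.

## The simulator: what it emulates, and what it does not

`simulatePopulation` realises the segregation model directly rather than
through a pedigree. Each heterogametic individual carries one sex-linked
haplotype; along each arm of the SDR chromosome the distance from the SDR
midpoint to the first crossover is geometric with the per-bp rate $r$, so
the sex-linked allele is retained at distance $D$ with probability
$(1-r)^D$ — and retention is *nested* along an arm, which is what gives
inter-locus r² its distance decay. For two loci at retention probabilities
$p_1 \ge p_2$ on the same arm the model's pairwise expectation is

$$ r^2 = \frac{p_2 (1 - p_1)}{p_1 (1 - p_2)}, $$

a closed form the acceptance suite uses as the generative-truth oracle
for half-decay recovery. SDR-internal loci are fully linked; loci on
other chromosomes are Hardy–Weinberg draws with Beta-distributed allele
frequencies. Genotyping error is a symmetric one-step dosage perturbation
(0↔1↔2), the simplest mechanism that degrades perfect segregation toward
the imperfect proportions real studies report; missingness is uniform;
both are applied last. Site annotations give exactly
`round(failFraction × n)` sites one threshold-violating value, with
passing values drawn well inside the passing region to avoid boundary
ambiguity. Expression counts are negative-binomial with the testis mean
multiplied by $2^{\mathrm{log2FC}}$ for planted genes.

Defaults mirror the study design this package targets: 215 females and 72
males, one SDR, XY segregation, a few percent error and missingness, and
a 3-vs-3 gonadal expression design. One master seed drives everything;
per-stage child seeds are derived at fixed offsets so stages reproduce
independently, and identical seeds give bit-identical output.

What the simulator does **not** emulate — and what passing tests
therefore cannot show about real data: background LD among autosomal loci
(loci off the SDR chromosome are independent, so genome-wide decay curves
are informative only on the SDR chromosome; real populations have
demographic LD everywhere), population structure beyond what PCA sees in
random data, read-level artefacts (the error model is genotype-level),
allele-frequency spectra shaped by selection or demography, and
polygenic or environmental sex determination. A correct XY call on
simulated data shows the decision machinery is sound, not that any
particular wild population is XY.

## Problem sizes and determinism in the test suite

The suite runs the null-scan property at 200 individuals × 10,000 sites,
system recovery on 100 datasets of 200 individuals × 100 SDR loci at 5%
error, and half-decay recovery on 500 males with ~170 informative loci —
sizes at which the Monte-Carlo bands in the assertions (3 standard
errors, one bin width) are meaningful yet the whole suite stays fast. All
stochastic tests fix their seeds. Oracles are kept independent of the
code paths they check: dense eigendecompositions for PCA, hand-solved
normal equations for the scan, exhaustive per-site re-checks for filters,
brute-force clustering and interval overlap for windows and genes, hand
tallies for zygosity, and `stats::t.test` loops for the DE stage.

## Known limitations

* The linear-model scan is a score-test approximation for a binary trait;
  odds-ratio-scale effect sizes require the (intentionally omitted)
  logistic variant, and kinship-aware mixed models are out of scope.
* The half-decay estimate inherits the bin width as its resolution; very
  sparse data can leave bins empty and the half point unreached, which is
  reported as `NA` rather than extrapolated.
* Marker validation assumes the validation cohorts were genotyped at the
  discovery variant; there is no liftover or local re-genotyping.
* The DE stage trades power for transparency; with pooled RNA libraries
  (n = 3 per group) marginal DEGs will be missed at p < 0.05.
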