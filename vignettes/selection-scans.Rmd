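---
title: "Selection-signature scans in structured populations: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-signature scans in structured populations: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sweepscan)
```

sweepscan detects genomic regions under recent positive selection among
closely related subpopulations of one breed or species, where the
differentiating signal is subtle: a few tens of generations of directed
breeding on top of shared ancestry. It combines three complementary scans —
an allele-frequency scan (windowed F~ST~/d~i~), a haplotype-differentiation
test (FLK/hapFLK), and a within-subpopulation local-haplotype-sharing scan —
and merges their significant windows into regions of interest (ROI) that are
intersected across methods and annotated with genes. This vignette explains
each model, the tunable parameters, the synthetic-data generator used for
validation, and the numerical and design choices that were genuinely open.

## Windowed F~ST~ and the d~i~ statistic

Per SNP and subpopulation pair, the package computes the Weir–Cockerham
(1984) two-population variance components $a$ (among populations) and
$a+b+c$ (total), from genotype counts including observed heterozygosity.
Windows are non-overlapping 10 kb intervals anchored at position 1 of each
chromosome (1-based closed, `[10000k+1, 10000(k+1)]`); the window F~ST~ is
the **ratio of sums** of components over the window's informative SNPs, not
the mean of per-SNP ratios — per-SNP ratios are unstable for low-MAF SNPs
and the ratio-of-sums is the standard windowed estimator. Negative window
values are kept: truncating at zero would bias the standardization below.

For subpopulation $i$ and window $w$,

$$d_i(w) = \sum_{j \ne i} \frac{F_{ST}^{ij}(w) - \mathrm{E}[F_{ST}^{ij}]}
{\mathrm{sd}[F_{ST}^{ij}]},$$

the sum over all other subpopulations of the pairwise window F~ST~
standardized by that pair's genome-wide moments. Standardizing per pair
discounts divergence explained by the overall relationship between the two
subpopulations, so large $d_i$ flags windows where $i$ specifically has
drifted away. Two numerical choices make the construction exact:

* moments are computed over the windows that are informative for **every**
  pair (one common window set), so the genome-wide mean of $d_i$ is exactly
  zero per subpopulation — with per-pair window sets the identity would hold
  only approximately;
* the standard deviation uses the population formula (divisor $N$), fixed
  for reproducibility.

Significance is empirical: the top `top_fraction` (default 0.001, the top
0.1%) of windows per subpopulation, $k = \lceil 0.001\,N \rceil$, with ties
at the cutoff broken by (chromosome, start) ascending so the selection is
deterministic. Significant windows within 500 kb (edge-to-edge, inclusive)
merge into one ROI; merging is single-linkage, idempotent and
order-invariant.

## FLK and hapFLK

FLK tests whether allele frequencies across subpopulations deviate from the
drift expectation encoded in a population kinship matrix $F$. The ancestral
frequency is estimated by generalized least squares,
$\hat p_0 = (\mathbf 1^\top F^{-1} p)/(\mathbf 1^\top F^{-1} \mathbf 1)$, and

$$T = (p - \hat p_0 \mathbf 1)^\top [\hat p_0 (1-\hat p_0) F]^{-1}
(p - \hat p_0 \mathbf 1)$$

is referred to a $\chi^2$ with $n_\text{pops}-1$ degrees of freedom.
Singular $F$ falls back to a Moore–Penrose pseudo-inverse with a warning.

The kinship matrix comes from population-based Reynolds distances and a
neighbor-joining tree, midpoint-rooted because no outgroup is assumed:
$F_{ij}$ is the branch length shared from the root to the most recent common
ancestor of leaves $i$ and $j$, and $F_{ii}$ the root-to-leaf length.
Negative NJ branch lengths are clipped to zero. Two calibration details
matter and are easy to get wrong:

* the classic Reynolds coancestry between two populations estimates the
  *average* of their drift coefficients, $(f_i+f_j)/2$, not the additive
  path length $f_i+f_j$ a tree-fitting method needs. `reynolds_dist_matrix()`
  therefore returns twice the (sample-size bias-corrected) coancestry by
  default, so NJ branch lengths estimate per-population drift directly;
* sample allele frequencies carry binomial noise on top of drift,
  $\mathrm{Var}(\hat p_i) = p_0(1-p_0)[f_i + (1-f_i)/m_i]$ with $m_i$
  called alleles. `flk_scan()` adds the $(1-f_i)/m_i$ term to the kinship
  diagonal by default. Without these two corrections the null mean of $T$ is
  inflated roughly two-fold at typical sample sizes.

Even so, the $\chi^2$ null is an approximation: Balding–Nichols frequencies
are beta-distributed and bounded, so the null mean of $T$ deviates from
$n_\text{pops}-1$ by a term of order the drift level (about 2% at
$F = 0.05$ in our measurements, with the 5% rejection rate near 0.043–0.046).
This is precisely why hapFLK practice computes empirical p-values; the
package's tests allow a 5%-relative band on the null mean rather than a pure
Monte-Carlo tolerance. Note also that kinship estimated *after* MAF
filtering is mildly inflated by ascertainment; FLK results at the stringent
$-\log_{10} p > 4$ threshold are insensitive to this, and hapFLK is
standardized empirically (below).

hapFLK replaces SNP allele frequencies with local haplotype-cluster
frequencies from the LD model (next section). At each marker, the FLK
quadratic form is evaluated for each cluster's frequency vector and summed,
scaled by $(K-1)/K$ because the $K$ cluster frequencies sum to one and carry
only $K-1$ degrees of freedom; with $K=2$ the statistic reduces exactly to
biallelic FLK, which the tests verify numerically. The statistic is averaged
over the EM restarts. P-values come from a genome-wide robust
standardization (median/MAD, normal upper tail): the original hapFLK
distribution's helper script is not specified in the literature this package
follows, so the package documents its own empirical-null convention instead
of imitating an unspecified one. Significance uses $-\log_{10} p > 4$.

## The haplotype-cluster LD model

The LD model is a fastPHASE-style hidden Markov model fit to **unphased**
genotypes. The hidden state of a diploid individual at marker $m$ is the
unordered pair of haplotype clusters its two chromosomes copy from (the
implementation works on ordered pairs, $K^2$ states, which is equivalent and
simpler to vectorize). Cluster $k$ emits the alternate allele with
probability $\theta_k(m)$; a genotype emission is the convolution of two
Bernoullis, and missing genotypes emit probability 1. Between adjacent
markers each haplotype chain jumps with probability $\rho(m)$ and lands in
cluster $k$ with weight $\alpha_k(m)$; chromosome boundaries force
$\rho = 1$, which makes chromosomes independent.

Fitting is EM with exact M-steps for $\theta$, $\rho$ and the per-marker
$\alpha$ (from expected jump-destination counts); at markers with negligible
expected jump mass the previous $\alpha$ is kept — a generalized EM step
that preserves the monotone log-likelihood, which the tests assert on every
fit. Defaults: 100 maximum iterations, relative log-likelihood tolerance
1e-6, $\theta$ initialized at the pooled frequency plus uniform jitter,
$\rho$ initialized at 0.05, `n_fits` random restarts seeded `seed + fit - 1`.
`K = 10` clusters follows common practice for within-breed panels; `n_fits`
defaults to 5, which at the problem sizes used here ranks restarts reliably
by likelihood (20 restarts reproduces heavier published practice and is a
single argument away). Restarts matter for a structural reason: EM can stall
in local optima where the cluster labels swap partway along a chromosome
("domain walls", visible as a spike in fitted $\rho$); wall-free fits have
distinctly higher likelihood, so keeping the best of several restarts
removes them, and averaging the hapFLK statistic over restarts damps what
remains. All downstream statistics are invariant to cluster relabeling, and
the tests check this by permuting fitted clusters.

Degenerate cases: $K=1$ collapses to the independent-SNP binomial
likelihood (asserted exactly); $\theta$ is clamped to $[10^{-6}, 1-10^{-6}]$
to keep emissions finite.

## Local haplotype sharing

Within one subpopulation, the sharing score at marker $m$ is the cluster
homozygosity $s(m) = \sum_k f_k(m)^2$ — the probability that two random
haplotypes descend from the same latent cluster, with $f_k(m)$ the
subpopulation's expected cluster frequency from the HMM posteriors,
averaged over restarts. $s$ ranges from $1/K$ (uniform usage) to 1 (one
shared ancestral haplotype); a sweep drives it toward 1 locally.

This score is deliberately a **proxy**: the Bayesian local-haplotype-sharing
machinery it stands in for (two-layer cluster models scored by Bayes
factors) is a larger model whose full specification lies outside this
package's sources. The proxy preserves the downstream role — confirming that
candidate regions sit on shared ancestral haplotypes — and every output
labels the score as cluster homozygosity. Significance standardizes the
track genome-wide (median/MAD), flags markers whose normal upper-tail
$-\log_{10}$ probability exceeds 5 (the empirical-tail analog of a
log~10~ Bayes-factor cutoff), and removes "orphan" runs shorter than 2
markers, since an isolated SNP does not evidence a haplotype.

One honest caveat, documented rather than hidden: drift alone produces
genuine local sharing peaks, so the flagged fraction on null panels is not
the nominal Gaussian tail (we measure a mean of about 1.5% flagged markers
over ten null panels at desk scale, most panels flagging nothing). This
mirrors real scans, where up to a few percent of SNPs per subpopulation
reach the sharing threshold; the scan is a confirmation layer, not a
calibrated test, and the cross-method consensus treats it as such.

## The synthetic-data generator

`simulate_panel()` generates the statistical structure the scans assume,
with recorded ground truth:

* **Hierarchical drift.** Ancestral frequencies uniform on $[0.05, 0.95]$;
  each branch of a two-level hierarchy draws from the Balding–Nichols beta
  with parameters $p(1-F)/F$ and $(1-p)(1-F)/F$. The closed-form consequence
  $\mathrm{E}[F_{ST}] \approx F$ between subpopulations of one group makes
  the generator testable against theory, which is why Balding–Nichols was
  chosen over forward simulation.
* **Mosaic LD.** Each subpopulation has a founder-haplotype pool; sampled
  haplotypes copy founders with per-bp switch intensity
  `copying_switch_rate` (default 2e-5, giving haplotype blocks of tens of
  kb at the default SNP density, the scale of within-breed LD). Founder
  allele counts are stochastically rounded to match the subpopulation
  frequency, so the finite pool adds no drift of its own; the default pool
  of 100 founders keeps the residual term (order $1/K_\text{founders}$)
  negligible against `drift_f` while preserving blocky haplotypes. This is
  what makes the Balding–Nichols expectation hold to three decimals in the
  acceptance measurements.
* **Sweeps.** Within a sweep interval, `favored_fraction` of the target
  subpopulation's haplotypes are forced to copy one favored founder. This
  produces *both* signal classes at once — an allele-frequency shift (for
  d~i~/FLK) and a long shared haplotype (for hapFLK/LHS) — mirroring how a
  real sweep presents, and the truth table records the realized
  favored-founder allele frequency per subpopulation.
* **Missingness** is uniform at random (default 1%), present only to
  exercise QC and per-SNP sample-size handling; real missingness is not
  random, and no conclusion here depends on its pattern.

What the generator does **not** emulate: coalescent genealogies,
recombination-rate variation, mutation, ascertainment of array SNPs, or
admixture. Passing tests therefore show that the statistics behave as their
theory predicts under drift + mosaic LD + forced sweeps; they do not show
robustness to demographic misspecification on real data.

Default scales are desk-sized (a few thousand SNPs, 2–6 subpopulations of
20–50 diploids; the acceptance measurements use up to 12,000 SNPs and the
sweep-recovery suites 10–20 replicate seeds). These sizes were chosen so the
Monte-Carlo error of each measured quantity is comfortably below the band it
is compared against.

## Input handling and QC

PLINK PED/MAP and VCF (GT field, biallelic) are supported. One PED subtlety
is documented on `read_plink()`: dosages are recoded by the first-seen
allele, and since PED carries no REF/ALT declaration, a marker whose first
called genotype is homozygous-alternate reads back orientation-flipped
(`2 - dosage`). The genotype configuration is always preserved, every scan
statistic is invariant to allele-label flips, and VCF round trips are
orientation-exact.

Marker QC removes, attributing each marker to its first failing filter in a
fixed order (non-autosomal, call rate < 0.95, pooled MAF < 0.05); boundary
values are retained because removal is strict `<`, and MAF is pooled across
all individuals rather than per subpopulation. QC is idempotent.

## Consensus and annotation

`sharing_matrix()` reports which significant windows are shared across
subpopulations (membership matrix, multiplicity histogram, pairwise
counts); `method_overlap()` reports the fraction of one method's ROI
overlapped (≥ 1 bp) by another's; `annotate_genes()` intersects ROI with
BED (0-based half-open, normalized on read) or GFF3 gene annotation and
counts distinct genes per subpopulation — a gene hit by two ROI of one
subpopulation counts once. All exports state their coordinate convention.

## Known limitations

* The $\chi^2$ FLK null and the normal-tail hapFLK/LHS analogs are
  approximations, quantified above; genome-scale empirical nulls are the
  robust choice on real data.
* The LHS score is a homozygosity proxy, not a Bayes factor; its threshold
  is an empirical-tail analog.
* The generator's realism stops at drift + mosaic LD; no coalescent or
  demographic inference is attempted.
* Sample-level QC and genotype imputation are out of scope: the package
  expects imputed or complete-enough genotypes.

```{r example}
sw  <- sweep_spec("pop1", chrom = 1, start = 9e5, end = 1.1e6)
cfg <- sim_config(n_subpops = 3, samples_per_subpop = 25,
                  n_chromosomes = 2, chrom_length = 2e6,
                  n_snps_per_chrom = 1500, sweeps = list(sw), seed = 42)
sim <- simulate_panel(cfg)
qc  <- apply_qc(sim$panel)
di  <- compute_di(window_fst(qc$panel))
sig <- significant_windows(di, top_fraction = 0.01)
roi <- merge_windows(sig$pop1, method = "di", subpop = "pop1",
                     stat_col = "di")
evaluate_recovery(roi, sim$truth)
```
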