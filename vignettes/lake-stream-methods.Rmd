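---
title: "Methods: permutation inference and population genetics for lake-stream divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation inference and population genetics for lake-stream divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakestream)
```

## What this package computes

Threespine stickleback (*Gasterosteus aculeatus*) living in a large
pre-alpine lake and its tributary streams diverge repeatedly in life
history: lake fish breed at greater age and body size, with multi-fold
higher fecundity, while stream fish shift to an essentially annual life
cycle. `lakestream` implements the complete inferential machinery for
this kind of replicated lake-stream comparison:

1. **Permutation tests with bespoke statistics** for habitat contrasts in
   age, body size, fecundity, egg size, plate-morph frequencies, and the
   among-population variability of mean body size.
2. **Landmark-based centroid size**, the body-size metric.
3. **Multi-allelic Weir-Cockerham F~ST~** between population pairs, with
   permutation P-values and Hedrick's standardized F'~ST~ via
   maximum-differentiation allele recoding.
4. **Mitochondrial haplotype collapsing** and a distance-based
   minimum-spanning haplotype network.
5. A **synthetic-data module** that generates all four input kinds with
   the statistical structure the analyses assume, so the whole pipeline
   is testable end to end without any external data.

## The permutation framework

Every test randomizes the response over the predictor: the grouping
labels are re-shuffled uniformly without replacement $B$ times and the
statistic $T$ recomputed. With $n_\mathrm{ext}$ replicates at least as
extreme as the observed value (ties count as extreme),

$$p = \frac{n_\mathrm{ext} + 1}{B + 1}.$$

The add-one convention makes the attainable floor exactly $1/(B+1)$:
$10^{-4}$ at the default $B = 9999$ for phenotype tests, $10^{-3}$ at
$B = 999$ for F~ST~. This convention was adopted because it is the only
one under which those conventional floors are attainable, and because it
yields valid (slightly conservative) P-values at any $B$.

**Sidedness.** Signed difference statistics (group mean differences,
variance-of-means differences) are tested two-sided on $|T|$; the
direction of divergence is reported separately through the sign of the
observed statistic. Chi-square and ANOVA-F are inherently non-negative
and tested one-sided on $T \ge T_\mathrm{obs}$. Two-sidedness for the
difference statistics is a deliberate, conservative choice; a one-sided
variant is available through the statistic functions directly.

**Permutation unit.** For all individual-level traits the unit is the
individual. For the global body-size comparison the response is a vector
of *population mean* sizes and habitat is a population-level label, so
whole populations are permuted. Fecundity and egg-size tests pool
individuals across sites within habitat before permuting, because
clutch data are sparse at single sites.

**Exact mode.** For small two-group instances `perm_test(..., exact =
TRUE)` enumerates all $\binom{n}{n_A}$ assignments and returns the exact
permutation P-value; the Monte-Carlo path is validated against it in the
test suite.

**Reproducibility.** One pipeline seed governs a run; each test derives
an independent substream via a string hash of (test name, system), so
adding or reordering tests never perturbs other results, and the derived
seeds stay below $2^{31}$.

**Power note.** The variance-of-population-means contrast has limited
power at realistic design sizes (about nine lake and eight stream
populations): with only 17 exchangeable units and heavy-tailed
permutation nulls, P-values fluctuate widely between replicate draws
even under a 16-fold true variance ratio. Marginal results in this test
should be read accordingly.

## Centroid size

For landmarks $x_1, \dots, x_L$ with centroid $\bar{x}$,

$$\mathrm{CS} = s \cdot \sqrt{\sum_{i=1}^{L} \lVert x_i - \bar{x} \rVert^2},$$

where $s$ is the pixel-to-mm scale. This is the standard
geometric-morphometrics size measure: invariant to translation and
rotation, linear in scale. No Procrustes superimposition is performed —
only size is analyzed, not shape. Egg size is total clutch dry mass
divided by egg count (mg per egg).

## Weir-Cockerham F~ST~ and standardization

For each locus and each allele, the 1984 method-of-moments variance
components are computed from the two populations' sample sizes $n_i$,
allele frequencies $p_i$ and observed heterozygote proportions $h_i$
($r = 2$): $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals). The multi-locus estimate is
the **ratio of sums**

$$\hat\theta = \frac{\sum_{\ell}\sum_{A} a_{\ell A}}
                    {\sum_{\ell}\sum_{A} (a+b+c)_{\ell A}},$$

not an average of per-locus ratios — the combination the original
reference recommends and the one standard microsatellite software
implements. Loci monomorphic across both populations are skipped (they
contribute exactly zero and would otherwise produce 0/0); per-locus
sample sizes adjust to missing calls; small negative estimates are
reported as computed. Pairwise matrices are computed pair by pair on the
two populations involved, never sliced from a global estimate.

P-values permute **whole multilocus individuals** between the two
populations, preserving sample sizes and within-individual linkage,
one-sided on $\hat\theta$, with the same add-one convention
(floor 0.001 at $B = 999$).

Because F~ST~ is bounded by within-population heterozygosity, raw values
understate differentiation at highly polymorphic markers. The
standardized value divides by the maximum achievable: every allele is
recoded to a population-private label (consistently within, disjointly
across populations), which preserves each population's frequency
spectrum and heterozygosity while removing all sharing; then

$$F'_{ST} = \hat\theta / \hat\theta_{\max}.$$

Recoding is pairwise (each pair recoded on its own data); the
standardization is undefined and flagged when
$\hat\theta_{\max} \le 0$. Note that for a weakly differentiated pair
$\hat\theta$ can be slightly negative, in which case the ratio is
slightly negative too — the bound $F'_{ST} \ge \hat\theta$ holds for
non-negative estimates.

## Haplotypes and the network

Aligned control-region sequences collapse to haplotypes; segregating
sites are alignment columns with at least two observed bases among
A/C/G/T. Under the default `mask` policy, N and gap characters are
treated as missing and excluded from both haplotype identity and
distances (a `strict` policy is available). Output coordinates are
1-based.

The genealogy is visualized as a **minimum-spanning tree** over pairwise
Hamming distances, with deterministic lexicographic tie-breaking. This
replaces likelihood genealogy inference deliberately: for a handful of
segregating sites a Hamming MST recovers the same topology class, is
exactly testable (the suite checks it against brute-force enumeration of
all spanning trees), and requires no model selection. Median-joining
reticulations and likelihood trees are out of scope.

## The synthetic-data module

The generators define the study conditions under which the pipeline is
exercised and tested:

* **Phenotypes.** Streams are essentially annual
  (ages 2/3/4 with probabilities 0.95/0.05/0), lake fish mostly in their
  third calendar year (0.10/0.85/0.05). Per-age size means are chosen so
  the overall habitat means are **80.4 mm (lake)** and **63.2 mm
  (stream)**; the within-age SD of 5 mm is a free parameter (real
  per-age spreads are not published as numbers). Mass is allometric,
  $4.9\times10^{-6}\,\mathrm{CS}^3$ with lognormal noise, giving habitat
  means near 2.5 g and 1.2 g. Female fecundity is
  $\max(0, \mathrm{round}(-604.2 + 11.05\,\mathrm{CS} + \varepsilon))$,
  $\varepsilon \sim N(0, 30^2)$ — the line through (63.2 mm, 94 eggs)
  and (80.4 mm, 284 eggs). The zero-floor slightly inflates the realized
  stream mean relative to the 94-egg anchor; the Gaussian error model is
  itself an assumption, since no error model is published. Per-egg dry
  mass (0.4 mg, lognormal noise) is identical in both habitats, so the
  egg-size test should and does come out null.
* **Microsatellites.** Balding-Nichols island model: ancestral
  frequencies from a symmetric Dirichlet, population frequencies from
  $\mathrm{Dirichlet}(p\,(1-F)/F)$, Hardy-Weinberg within populations.
  Chosen because its single parameter $F$ is exactly the quantity the
  estimator targets, giving a clean recovery benchmark (8 loci, 10
  alleles, 25 diploids per population recover $F \in \{0.02, 0.10,
  0.20\}$ within $\pm 0.02$ on average). All populations are exchangeable
  under this model — it does **not** emulate the empirical pattern of
  near-zero differentiation among lake samples.
* **D-loop.** A random 305-bp backbone with 6 substitutions defining 5
  haplotypes. A pure star of single-step branches cannot produce fewer
  haplotypes than SNPs + 1, so the generator distributes the mutant
  columns over `n_hap - 1` branches (lengths as even as possible; with
  `n_hap = n_snp + 1` it reduces to the classic star; a chain topology is
  available). Default per-population frequencies make one haplotype
  predominant basin-wide, fix a second in the out-of-basin sample, and
  place rare haplotypes in stream samples at frequency 0.1-0.3 — rare
  enough to be stream-private, common enough that all five haplotypes
  are observed with high probability at the configured sample sizes
  (256 sequences).
* **Diet.** Dirichlet-multinomial around per-site mean proportions over
  seven prey classes with concentration 4 (matched to the published
  SD magnitudes); printed mean vectors that do not sum exactly to 1
  because of rounding are normalized. Totals are Poisson(20).

What the generators do **not** emulate: temporal/spatial autocorrelation
within sites, allele-size homoplasy and stepwise mutation of real
microsatellites, linkage, recombination-free coalescent genealogy of the
mitochondrial data, and the empirical lake-panmixia/stream-isolation
F~ST~ structure. Passing tests therefore demonstrate correctness of the
estimators and tests under their stated models, not robustness to those
real-data features.

## Numerical choices

* Extremeness comparisons use a relative tolerance of $10^{-12}$ so
  float jitter cannot flip tie counting.
* A constant response gives $p = 1$ with a warning; degenerate
  contingency tables give statistic 0 with a warning; ANOVA with zero
  within- and between-variance gives 0 with a warning, and
  zero-within/positive-between gives `Inf` (counted extreme only against
  itself).
* Undefined $\hat\theta$ (all loci monomorphic) and undefined
  standardization ($\hat\theta_{\max} \le 0$) are signalled, and the
  pairwise matrix propagates `NA` entries rather than aborting.
* Report display rounds F~ST~ to 2 decimals with P in parentheses;
  machine-readable companions keep full precision.

## Problem sizes used by the test and acceptance runs

Simulation-based checks run at deliberately modest sizes chosen for
tight Monte-Carlo bands at interactive runtimes: 1000 null datasets at
$B = 199$ for engine calibration; 200 replicates per $F$ level for
parameter recovery; 100 pairs for the standardization sweep; exhaustive
enumeration for 3v3/4v4 permutation oracles, 2v2 F~ST~ permutation and
spanning trees up to 6 nodes. The full pipeline drivers use the study's
sample-size table (283 individuals, 11 samples, 256 sequences) with
$B = 9999$ / $B = 999$.

## Known limitations

* Global (k-population) $\theta$, bootstrap confidence intervals over
  loci, R~ST~ and exact tests of differentiation are not implemented.
* Admixture-clustering inference is out of scope (it is the domain of
  dedicated published tools, not re-implemented here).
* The MST is a tree: reticulate alternatives at equal parsimony are
  resolved deterministically, not displayed.
* The variance-of-means test's power limitation discussed above.
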