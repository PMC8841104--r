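---
title: "Interaction-sensitive gene set enrichment for SNP data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-sensitive gene set enrichment for SNP data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episgsea)
```

## The problem

Standard pathway analysis of genome-wide SNP data ranks variants by a
univariate association statistic, aggregates variant scores to genes, and
asks whether high-scoring genes concentrate in predefined gene sets.
Purely epistatic architectures — where the joint genotype at two loci
shifts disease risk while every single locus shows no marginal effect —
are invisible to that pipeline by construction: the univariate statistic
has nothing to see.

`episgsea` replaces the univariate ranking with Relief-based feature
importance (MultiSURF and MultiSURF\*), which scores each SNP by how its
genotype differences between near (and far) neighbours track phenotype
differences, and therefore responds to interactions without an exhaustive
pairwise search. Everything downstream — SNP-to-gene aggregation,
pre-ranked competitive GSEA with a gene-set permutation null, FDR
estimation, leading-edge analysis — is shared between the univariate and
Relief branches, so the two strategies can be compared end to end. A
simulator of pure two-locus epistasis provides ground truth for that
comparison.

## Pure two-locus penetrance models

A two-locus model over biallelic loci A and B with minor allele
frequencies $m_A, m_B$ is a $3\times 3$ penetrance table
$f_{ij} = P(\text{case} \mid g_A = i, g_B = j)$, $i,j \in \{0,1,2\}$
counting copies of the minor allele. With Hardy–Weinberg genotype
frequencies $p_i, q_j$, the model's prevalence and (broad-sense, binary
scale) heritability are

$$K = \sum_{ij} p_i q_j f_{ij}, \qquad
h^2 = \frac{\sum_{ij} p_i q_j (f_{ij} - K)^2}{K(1-K)}.$$

The model is *pure* (strictly epistatic) when both single-locus marginal
penetrances are flat: $\sum_j q_j f_{ij} = K$ for every $i$ and
$\sum_i p_i f_{ij} = K$ for every $j$. Purity implies
$P(g_A = i \mid \text{case}) = p_i$: cases and controls have identical
single-locus genotype distributions, so no univariate statistic carries
signal.

### Generating models with exact heritability

`gen_penetrance_model()` treats the deviations $d_{ij} = f_{ij} - K$ as a
9-vector. The six purity constraints form a rank-5 linear system, leaving
a 4-dimensional null space (computed once by SVD). The generator draws a
standard-normal coefficient vector in that null space, rescales the
resulting deviation pattern by the unique positive factor that sets
$h^2$ to the target exactly, and accepts the draw iff all nine
penetrances stay inside $[0,1]$; otherwise it resamples (capped at
10,000 tries). The returned table satisfies the purity residuals and the
heritability target to $10^{-9}$, and the whole procedure is a direct,
deterministic-given-seed construction rather than a stochastic search
over tables.

Feasibility is a real constraint here: purity plus the $[0,1]$ box bound
the attainable heritability. At MAF 0.2 the maximum $h^2$ of a pure model
is about 0.34 at $K = 0.25$ and about 0.47 at $K = 0.40$ (computed by
enumerating the vertices of the constraint polytope, where the maximum of
the convex heritability functional must lie). The package default is
$K = 0.35$, the region where the $h^2 = 0.4$ design used throughout the
examples is comfortably feasible and rejection sampling accepts a few
percent of draws. Prevalence is exposed everywhere (`K` argument) since
it is a free parameter of the design rather than something the analysis
estimates.

## The simulated study design

`epistasis_architecture()` builds the standard design used in the
package's tests: four pure two-locus pairs (MAF 0.2, $h^2 = 0.4$ each,
shared $K$), 1000 no-effect SNPs, 405 cases and 405 controls. The eight
functional loci carry the symbols of eight genes from the GO category
*negative regulation of mRNA splicing* (PTBP1, U2AF2, SRSF9, SFSWAP,
PCBP4, NPM1, C1QBP, SAP18), so a gene-set analysis has a ground-truth
pathway to recover. Noise SNPs draw a MAF once each from
Uniform(0.05, 0.5) — the post-QC allele-frequency range of a typical
imputed array panel — and all genotypes are sampled independently under
HWE.

### Combining several pairs additively

With $M$ pairs each contributing "one $M$-th of the effect", two readings
are possible, and `simulate_dataset(combine = )` implements both:

* `"scaled_sum"` (default):
  $P(\text{case}\mid g) = K + \tfrac{1}{\sqrt{M}}\sum_k (f_k(g) - K)$,
  clipped to $[0,1]$. Because the pair deviations are independent, the
  heritability of the simulated *outcome* equals the shared per-pair
  model heritability, and each pair contributes exactly $1/M$ of it.
* `"mean"`: $P(\text{case}\mid g) = \tfrac{1}{M}\sum_k f_k(g)$. Each
  pair's deviation is scaled by $1/M$, so its effective heritability
  shrinks to $h^2/M^2$ and the outcome heritability to $h^2/M$.

The scaled-sum rule is the default because it keeps the stated design
heritability (0.4) as a property of the simulated data. Under the mean
rule the four-pair design carries an outcome heritability of only 0.1
(0.025 per pair), which at 810 samples and 1008 SNPs leaves the
functional loci statistically indistinguishable from noise for every
scoring method — a regime in which the method comparison the simulator
exists to support becomes vacuous. Clipping under the scaled-sum rule is
rare at the default design (the summed scaled deviations seldom leave
$[0,1]$) and slightly perturbs purity in the far tails; the test suite
checks empirically that case MAFs at functional loci stay within
sampling error of the design MAF.

Rejection sampling fills the case and control quotas in vectorized
batches, so balanced designs are exact, and every run is reproducible
from its integer seed.

### What the simulator does not emulate

No linkage disequilibrium between simulated SNPs (each locus is drawn
independently), no covariates or population structure, no genotyping
error or missingness, and no higher-order (3+ locus) interactions. The
original array data it stands in for had LD pruned to $r^2 \le 0.2$
before analysis, which independence approximates from below. Passing
tests on this generator therefore demonstrate sensitivity to pure
interaction signal under idealized sampling — not robustness to the
correlation structure, stratification or missingness of real cohorts.

## Relief-based SNP scoring

Both algorithms work on the genotype mismatch distance between samples:
the fraction of jointly non-missing SNPs at which two samples differ
(`pairwise_distances()`). For each target sample $i$, the mean $\mu_i$
and population standard deviation $\sigma_i$ of its distances to all
other samples define adaptive neighbourhoods:

* **near**: $d_{ij} < \mu_i - \sigma_i/2$,
* **far**: $d_{ij} > \mu_i + \sigma_i/2$.

For MultiSURF, each feature $a$ accumulates, per target,
$$\Delta_i(a) = \frac{1}{|M_i|}\sum_{j \in M_i} \mathrm{diff}(a,i,j)
             - \frac{1}{|H_i|}\sum_{j \in H_i} \mathrm{diff}(a,i,j),$$
where $H_i$ / $M_i$ are the near hits (same class) and near misses
(different class), a term being dropped when its set is empty. The final
score is $\sum_i \Delta_i(a) / n$, which bounds scores to $[-1,1]$.
Intuition: genotype differences across the class boundary among close
neighbours are evidence *for* a feature; differences within a class are
evidence *against* it.

MultiSURF\* adds the far neighbourhood with inverted sign — far hits with
differing values increment, far misses decrement, each averaged within
its group — and divides the summed near+far contribution by $2n$ so the
$[-1,1]$ bound still holds (near and far sums are each bounded by $n$;
the normalizing constant is a package choice since only the range, not
the constant, is part of the method's contract). The far region is where
pure interactions leave their imprint (instances that agree at an
interacting pair tend to be far apart yet share class), which is why the
starred variant trades univariate sensitivity for interaction
sensitivity.

Numerical choices: genotypes are compared as discrete values
(`diff` = 0/1 mismatch), matching how few-valued integer features are
treated in practice; a continuous $|a-b|/2$ difference is available via
`diff = "continuous"`. A missing genotype contributes `diff` = 0 (a
no-evidence rule) and sample pairs with no jointly observed SNPs are
excluded from $\mu_i$, $\sigma_i$ and all neighbourhoods. Neighbourhood
thresholds are strict inequalities; the compiled implementation
reproduces R's long-double mean so that threshold ties resolve
identically to a plain-R reference, and the test suite checks exact
agreement with an exhaustive oracle over hundreds of random datasets.
Scores are invariant to sample order, feature order (up to the matching
permutation) and swapping the class labels.

`cv_average_scores()` averages scores over the training portions of a
stratified $k$-fold split ($k = 10$ by default), damping the sampling
variance of a single Relief pass. Scoring the training portion (rather
than the held-out tenth) is the package's reading where the convention is
ambiguous; `on_held_out = TRUE` gives the alternative. The χ²
comparator (`chi2_scores()`) is the Pearson statistic on the 2×3
genotype table (or the 2×2 allele table in `"allelic"` mode), used purely
as a ranking statistic with no multiple-testing correction — exactly the
role it plays in the univariate branch it emulates.

## From SNPs to ranked genes

`map_snps_to_genes()` assigns a SNP to every gene whose body, extended by
a 10 kb window on each side, covers it. Coordinates follow fixed
conventions to avoid off-by-one drift: SNP positions are 1-based
($\mathrm{bp}_0 = \mathrm{bp} - 1$), gene intervals are 0-based
half-open (BED), and the window test is
$\mathrm{start} - w \le \mathrm{bp}_0 < \mathrm{end} + w$. Window bounds
apply to gene bodies (not transcripts), the mapping is strand-agnostic,
and one SNP may feed several overlapping genes. `gene_scores()`
summarizes each gene by the *maximum* of its SNP scores — the
high-water-mark convention of SNP-level GSEA — keeping negative Relief
scores as they are (flooring them at zero would discard the information
that a SNP argues against class relevance). Ranked lists sort by
descending score with lexicographic tie-breaks, so every downstream
result is deterministic. `rank_correlation()` compares two gene rankings
by Spearman's $\rho$ with average-rank ties on the intersection of their
universes.

## Pre-ranked GSEA with a gene-set permutation null

`enrichment_score()` is the weighted Kolmogorov–Smirnov-like running
sum: walking the ranked list, genes in the set add
$|s|^p / N_R$ (with $N_R$ the sum of $|s|^p$ over members, $p = 1$ by
default) and genes outside subtract $1/(N - N_H)$; the enrichment score
ES is the signed maximal deviation from zero (first occurrence on exact
ties). If every member has score exactly 0 the walk falls back to
unweighted increments with a warning. `filter_gene_sets()` first
intersects each set with the ranked universe and then applies the
inclusive 20–200 size rule.

`preranked_gsea()` builds the null per set from `n_perm` same-size
uniform gene draws (a concrete, documented instantiation of "permutation
by gene set" for a pre-ranked input), then:

* $\mathrm{NES} = \mathrm{ES} / \overline{|\mathrm{ES}_{null}|}$ over
  same-sign null values;
* nominal $p$ = fraction of same-sign null ES at least as extreme,
  floored at $1/(n_{perm}+1)$ so no p-value is exactly zero;
* FDR $q$ pools the sign-matched normalized null scores across all sets:
  $q = \Pr(|\mathrm{NES}_{null}| \ge |\mathrm{NES}|) /
       \Pr(|\mathrm{NES}_{obs}| \ge |\mathrm{NES}|)$,
  clipped to $[0,1]$ and made monotone non-increasing in
  $|\mathrm{NES}|$ within each sign.

The reference desktop tool leaves parts of its normalization and FDR
machinery unstated, so the implementation is documented formula-first as
above; numerical agreement with that tool is not claimed. The running-sum
statistic itself is cross-checked in the tests against an independent
implementation (`fgsea::calcGseaStat`), and permutation p-values are
verified to be uniform on a fully null ranked list.

Leading-edge genes are the set members at or before the running-sum peak
for positive ES (at or after it for negative ES).
`leading_edge_analysis()` restricts each analysis to its `top_n` sets by
$|\mathrm{NES}|$ (ties: smaller $q$, then set name), builds the binary
gene-by-set occurrence matrix, the per-set leading-edge fraction, and the
list of genes appearing on a leading edge in *every* supplied analysis —
the replication construction used to compare methods or cohorts.

## Pipeline and reproducibility

`run_pipeline()` chains the stages — (trio mode) pseudo-control
construction from the untransmitted parental alleles, optional control
balancing, LD pruning (defaults $r^2 = 0.2$, window 50 SNPs, step 5),
per-method scoring with CV averaging, gene mapping, per-method GSEA, the
between-method Spearman table, and the cross-method leading-edge
summary — writing every intermediate as a plain text table plus a JSON
manifest of configuration, seeds and record counts. One master seed
derives per-stage seeds by fixed offsets, so a stage can be re-run in
isolation and identical configurations produce byte-identical outputs.
Mendelian-inconsistent (trio, SNP) cells become missing with a warning
rather than aborting, on the view that residual inconsistencies after
upstream QC should not kill a run; the consistency check is the full
parental-transmission constraint (a homozygous parent always transmits
its allele), which is stricter than only requiring
$f + m - c \in \{0,1,2\}$.

## Problem sizes in the test suite

The heavier checks run at sizes chosen to make their statistical claims
meaningful while staying desk-scale: oracle equivalence on hundreds of
random datasets up to $30 \times 6$; score-range sweeps over 100 random
datasets up to $100 \times 50$; marginal-purity checks on 25,000
simulated cases; GSEA null calibration on 200 random sets at
$n_{perm} = 1000$; and five independent end-to-end runs of the full
four-pair design (810 samples, 1008 SNPs, three methods, 151 gene sets).

## Known limitations

* Gene-level max-score aggregation favours long genes (more SNPs, higher
  maxima); no gene-size correction is applied.
* The gene-set permutation null ignores inter-gene correlation (LD
  between neighbouring genes), as all competitive gene-resampling nulls
  do.
* Detection of a *single* planted pathway from a handful of interacting
  genes is near-binary at moderate sample sizes: the enrichment signal of
  a small set rests on its two or three best-ranked members, so q-values
  fluctuate strongly across simulation replicates even when the ranking
  methods behave as designed. Collections with redundant, overlapping
  sets (as in real GO analyses) spread that risk; a single isolated set
  does not.
* Relief scoring is $O(n^2 p)$; the compiled implementation handles the
  package's design sizes in seconds but genome-wide panels (millions of
  SNPs) require the LD-pruning and subsampling steps the pipeline
  provides.
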