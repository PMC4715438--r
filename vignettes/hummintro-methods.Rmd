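---
title: "Models and methods behind hummintro"
author: "hummintro authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hummintro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hummintro)
```

## The study system and what the package computes

`hummintro` implements the desk-scale computational chain used to study
introgression in a Mesoamerican hummingbird species complex: three
parapatric taxa (a berylline, a blue-tailed and a steely-blue form)
separated by two lowland barriers — the Isthmus of Tehuantepec and the
Nicaraguan Depression. Mitochondrial haplotypes are shared across the
barriers while nuclear microsatellites resolve three clusters, the classic
signature of recent divergence with gene flow. The package covers the
pieces of that analysis that are deterministic computations or
simulation-based tests: sequence diversity and neutrality statistics,
mismatch-distribution expansion fits, median-joining haplotype networks,
conversions of coalescent-scaled parameters to demographic units,
comparison of contemporary and historical migration matrices, Evanno
DeltaK and genotype PCA post-processing, a background-vs-occupied niche
divergence test, and a clinal plumage colour index. The heavy external
inference engines (Bayesian tree builders, isolation-with-migration and
assignment MCMC samplers, maximum-entropy distribution models) are out of
scope: the package consumes their summarised output.

Because the original field data are not bundled, a first-class synthetic
data module generates datasets with the statistical structure the analysis
assumes, so every stage is exercised end to end by the test suite.

## Sequence statistics

All statistics operate on a haplotype table obtained after complete
deletion of alignment columns containing gaps or ambiguity codes (the
default; pairwise deletion is deliberately not offered because every
downstream statistic assumes a single shared site set). With $n$ samples,
haplotype frequencies $\hat p_i$, haplotype diversity is the unbiased
$h = \frac{n}{n-1}\bigl(1 - \sum_i \hat p_i^2\bigr)$, and nucleotide
diversity $\pi$ is the mean pairwise difference per retained site over all
$\binom{n}{2}$ pairs.

**Tajima's D** uses the standard $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$
constants. Its p-value is obtained by simulating neutral coalescent
genealogies conditioned on the observed $(n, S)$ — $S$ mutations thrown on
the tree proportionally to branch length — and is two-tailed
($p = 2\min\{\Pr(D^* \le D), \Pr(D^* \ge D)\}$, capped at 1). The
"permutations" quoted for such tests in the population-genetics literature
are simulated coalescent replicates; the package follows that convention
with 1000 replicates by default.

**Fu's Fs** is $\ln\bigl(S'/(1-S')\bigr)$ with
$S' = \Pr(K \ge k_{obs} \mid \hat\theta, n)$ under the Ewens sampling
distribution, where $\hat\theta$ is the observed mean number of pairwise
differences. $\Pr(K = k) = |s(n,k)|\,\theta^k / \theta^{(n)}$ is evaluated
in log space via unsigned Stirling numbers of the first kind built by the
$|s(n+1,k)| = |s(n,k-1)| + n|s(n,k)|$ recurrence with log-sum-exp, so
samples of several hundred sequences pose no overflow problem. Both tails
are accumulated in log space, which keeps Fs finite and accurate when $S'$
is within machine epsilon of 0 or 1. The p-value is the one-tailed
$\Pr(F_s^* \le F_s)$ under neutral simulation at $\hat\theta$, the
convention under which Fs is interpreted (significance is conventionally
declared below 0.02; the package reports the raw fraction and leaves the
cut to the user). The test suite checks $S'$ against a Chinese-restaurant
process enumeration that shares no code with the Stirling route.

## The sudden-expansion mismatch model

The mismatch spectrum counts sample pairs differing at $k$ sites. Under a
sudden expansion, a population of scaled size $\theta_0$ jumped to
$\theta_1$ at $\tau$ mutational time units before the present. Rather than
the truncated-series textbook expression, the package evaluates the model
probabilities exactly by integrating the Poisson difference kernel against
the piecewise-exponential pair coalescence density:

$$F_k = \hat F_k(\theta_1)\, P\!\left(k+1,\ \tau\tfrac{1+\theta_1}{\theta_1}\right)
 + e^{-\tau/\theta_1} e^{\tau/\theta_0}\, \hat F_k(\theta_0)\,
   Q\!\left(k+1,\ \tau\tfrac{1+\theta_0}{\theta_0}\right),$$

where $\hat F_k(\theta) = \theta^k/(1+\theta)^{k+1}$ is the equilibrium
geometric and $P, Q$ are the regularised incomplete gamma functions. The
limits $\theta_0 = 0$ (instant ancestral coalescence, Poisson($\tau$)
wave) and $\theta_1 = \infty$ (no coalescence since the expansion) are
handled explicitly; `mismatch_model_probs()` exposes the curve.

Fitting minimises the sum of squared deviations (SSD) between observed
frequencies and $F_k$ over $k = 0..k_{max}$: a coarse grid over
$\tau \in [0, 2k_{max}]$ (with a small $\theta$ grid) seeds a Nelder-Mead
refinement on transformed parameters, with $\theta_0 \le \theta_1 \le 10^4$
enforced by construction. Harpending's raggedness index is
$\sum_k (x_{k+1}-x_k)^2$ on the normalised frequencies with an implicit
zero class appended. p-values are parametric-bootstrap: samples of the
same size are simulated under the fitted history (a piecewise-rate
coalescent in mutational units with Poisson half-rate mutations per
branch), each replicate SSD is recomputed **after refitting**, and p is
the fraction of replicates at or above the observed statistic. The
bootstrap default is 9000 replicates; the test suite uses 100-200 per fit,
which resolves p at the 0.01 level — ample for calibration checks at
$\alpha = 0.05$.

A degenerate spectrum (all pairs identical) returns a flagged
$\tau = 0$ fit with a warning instead of an optimisation failure.

## Median-joining networks

Haplotype networks are built from Hamming distances on retained sites.
The minimum spanning network (the union of all minimum spanning trees)
uses the minimax characterisation: an edge belongs to some MST iff its
weight equals the smallest maximum-edge weight over all paths between its
endpoints; the $\varepsilon$-relaxed network admits edges up to
$\varepsilon$ above that threshold. The median-joining iteration then
proposes quasi-median vectors (site-wise majority consensus, three-way
ties resolved to the lexicographically smallest state) for every triplet
with at least two links in the current network, adds the candidate that
most reduces the minimum-spanning cost of the node set (ties again
lexicographic), prunes median vectors whose removal no longer increases
that cost, and repeats to a fixed point. Total cost is non-increasing by
construction, the iteration therefore terminates, and all tie-breaking is
deterministic — two runs on the same input are identical, unlike the
order-dependent behaviour of legacy network software, which is
deliberately not emulated. $\varepsilon$ defaults to 0. Observed node
attributes carry per-population haplotype counts for pie-chart style
rendering; networks export to GML (via igraph) and a TSV edge list.

## Demographic conversions

Generation time follows $T = a + s/(1-s)$ from age at maturity $a$ and
adult annual survival $s$; with $a = 2$ the two survival scenarios used
for hummingbirds (0.30 and 0.52) give $T = 2.43$ and $3.08$ years. (A
literal reading of "maturity one year after hatching" would give $a = 1$,
but only $a = 2$ reproduces the published $T$ range, so 2 is the
default in examples.) Scaled divergence times convert as $t = B/U$ with
$U$ the per-locus per-year rate ($u \times$ locus length), and effective
sizes as $N_e = q/(c\,U\,T)$ with inheritance scalar $c = 4$ by default —
the $\theta = 4N_e\mu$ convention of isolation-with-migration software —
and $c = 2$ selectable for strict maternal haploid accounting; the
published table never states the formula, so the convention is explicit
and configurable. `rescale_ne()` re-expresses sizes between generation
-time assumptions as $N\,T_{old}/T_{new}$ with half-away-from-zero
rounding at the input's precision; note that independently rounded source
tables can disagree with such rescaling by one unit in the last digit.

Historical migration output scaled as $M = m/\mu$ converts to
per-generation fractions as $m = M\mu$. The package retains a
"paper-literal" division mode behind a flag (with a warning) because the
source text says "dividing"; division yields values above 1 that cannot
be fractions, and the choice is immaterial for correlation-based
comparisons. Migrants per generation are $N_e m = \theta M/4$.

The Mantel comparison of contemporary and historical matrices correlates
corresponding off-diagonal cells and permutes row and column labels of
the second matrix **simultaneously**, the correct null for asymmetric
matrices (which is why the symmetric-dissimilarity Mantel of vegan is not
used); when $n! \le$ the requested permutations the exact enumeration is
used and flagged. The p-value is two-tailed on $|r|$. For sampled
permutations the identity is included in the null set
($p = (1 + \#\{|r^*| \ge |r|\})/(B+1)$), keeping $p > 0$.

## Assignment post-processing

Evanno's $\Delta K$ is the replicate-mean absolute second difference of
$\ln P(K)$ divided by the replicate standard deviation at $K$, defined on
interior $K$ of a contiguous range with at least two replicates each; a
zero standard deviation is an error naming the offending $K$ rather than
an infinite statistic. Genotype PCA one-hot encodes each locus into
per-allele count columns (0/1/2), imputes missing genotypes to the column
mean (the standard choice that shrinks missing individuals toward the
grand centroid rather than toward any population), mean-centres without
scaling, and fixes each axis sign so its largest-magnitude loading is
positive, making results reproducible across platforms and locus
orderings.

## Niche divergence and conservatism

Variable pruning is a greedy scan in a user-controlled priority order
(the original study preferred the most "temporally inclusive" variable of
each correlated pair — that ordering is study-specific knowledge, so the
package takes an explicit priority list): a variable is kept iff its
absolute Pearson correlation with every kept variable is below the 0.7
threshold. Backgrounds are delimited by minimum convex polygons around
each group's occurrences and sampled uniformly by rejection; climate
values attach from the nearest record, emulating raster extraction on
synthetic climate fields.

The divergence test fits a PCA on the pooled background points of the two
groups — backgrounds define the *available* environmental space, which is
the reference the test needs — and projects occurrences onto those axes.
Variables are standardised to unit variance by default because bioclim
units are incommensurable. Per axis, the occupied divergence
$D_{occ} = |\bar s_A - \bar s_B|$ over occurrence scores is compared with
an interval of the background divergence recomputed over jackknife
replicates: 75% of each group's background points drawn **without
replacement** (the natural reading of "jackknife with 75% replacement"; a
with-replacement bootstrap mode is available behind a flag), with the
2.5% and 97.5% empirical quantiles bounding the null at
$\alpha = 0.05$ — the two-sided level implied by the paired bounds the
method reports. Classification is divergence above the interval,
conservatism below, none inside.

One property of this published test deserves emphasis: the null is
centred on the *realised* background divergence and its spread reflects
only subsampling jitter, so the test is approximately calibrated only
when the occurrence samples carry at least as much information as the
background subsamples (occurrences comparable in number to the
backgrounds). The package's calibration study therefore uses equal
occurrence and background sampling effort (100 points per group, 200
jackknife replicates, 100 seeds), where the false-divergence rate stays
at the nominal level; with backgrounds an order of magnitude larger than
occurrences — as in typical field use with 1000 background points — the
test is anti-conservative, a limitation inherent to the method rather
than to this implementation. Under a strong antisymmetric occupied offset
(±1.5 SD on one variable) the test detects divergence essentially always,
which the power study asserts at the 90% level over 50 seeds.

Elevation differences among groups use the Kruskal-Wallis rank test with
tie correction followed by Dunn's pairwise $z$ comparisons with
Bonferroni adjustment (written in-package; no installed package provides
Dunn's test).

## The plumage colour index

The published index sums ten plumage characters to a 0-24 scale with the
berylline extreme at 24 and the steely-blue extreme at 0; the exact
per-character scores live in supplementary material that prints only the
endpoints, so the default scheme is a design choice constrained by them:
the four diagnostic characters repeatedly discussed (rufous patch on the
secondaries, rufous patch on the primaries, belly colouration, tail
colouration) score 0-3 and six auxiliary characters score 0-2, giving
$4\times3 + 6\times2 = 24$. Intermediate states take intermediate integer
scores. The scheme is data: any named list of state-score vectors with
per-character minima of 0 can replace it, and all scoring is additive and
order-invariant by construction. Clinal structure is summarised by
equal-width longitude bins (mean ± sd of the index and of the four
diagnostic characters).

## Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical* structure the analyses assume,
with defaults chosen to mirror the study conditions:

* `sim_sequences()`: 2-3 demes (the three clusters), 50 haploid samples
  per deme (154 birds over three taxa), an 1100 bp locus (the combined
  mitochondrial matrix), per-site $\theta$ = 0.005 (observed $\pi$ was
  0.005-0.007), divergence 10,000 generations and migration $10^{-3}$ per
  generation (about one migrant per generation at the default deme size
  of 1000), under a discrete-generation structured coalescent: exact
  Wright-Fisher parent sampling (allowing the multiple mergers that large
  sample-to-deme ratios produce) while the per-generation event
  probability exceeds 0.05, geometric waiting-time jumps — the exact
  discrete waiting law under at most one event per generation — once
  lineages are few. Mutations are Poisson per branch at rate
  $\theta/(2N_e)$ per site with JC-style symmetric substitution on a
  finite sequence. No recombination, selection or rate heterogeneity.
* `sim_microsats()`: Balding-Nichols cluster frequencies around shared
  ancestral Dirichlet draws with concentration $(1-F)/F$, so realised
  Weir-Cockerham FST tracks the target (an in-package Weir-Cockerham
  estimator verifies this; no installed package provides one); a K-allele
  model by identity, not a stepwise size ladder, which suffices for the
  frequency-based downstream stages; 12 loci by default; admixed
  individuals draw each gene copy from a cluster chosen by their
  admixture fractions; missing genotypes coded -9 following
  STRUCTURE-format convention.
* `sim_landscape()`: per-group multivariate-normal climate around group
  centroids (19 variables by default), occurrences from the same
  distribution displaced by a configurable occupied offset, groups in
  disjoint longitude bands, and per-group elevations defaulting to the
  published means and SDs (1375±700, 921±526, 542±585 m). There are no
  spatially explicit rasters; climate is attached to points directly.
* `sim_plumage()`: expected character scores decline west to east through
  two logistic steps centred on the barrier longitudes (defaults -94.5
  and -85.5), from the full index at the western extreme to 0 at the
  eastern, with integer score noise.

Passing tests on these data demonstrate internal correctness and
statistical calibration of the implementations — not that real
hummingbird data satisfy the generators' assumptions (panmictic demes,
unlinked loci, normal climate, monotone cline).

## Numerical choices and problem sizes

All simulators and resampling procedures take explicit integer seeds;
there is no hidden global state contract, and identical configurations
produce byte-identical outputs. The test suite runs its calibration
studies at deliberately moderate sizes chosen as a sensible desk-scale
design: 200 neutral datasets with 200 conditional replicates each for
Tajima's D; 200 true-model datasets with 100-replicate parametric
bootstraps for the SSD; 100 seeds for the niche type-I study and 50 for
power; 30 replicate loci for the $\pi$-vs-$\theta$ convergence check;
full-enumeration oracles are kept at or below 7 network nodes, 18
sequences, and 3x3 Mantel matrices where exhaustive search is exact.

Known limitations: the mismatch SSD is compared over the observed
$k$ range only; the expansion fit's $\theta_1$ is capped at $10^4$ (the
pure-Poisson limit is available explicitly); the niche test's calibration
caveat above; and Evanno's $\Delta K$ requires balanced replicates per
$K$.
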