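---
title: "Models and methods behind EcoParallel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind EcoParallel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

EcoParallel asks a single scientific question from two directions: when the
same ecotype contrast (here, montane vs alpine plant populations) evolves
repeatedly at several localities, how much of the molecular response is
*reused* across the replicate divergence events? The package implements the
full analysis chain — demographic model selection to establish that the
replicates are indeed independent origins, differential expression per
ecotype pair, repeatability statistics over the resulting gene sets,
conditioned redundancy analysis for subtle multilocus expression shifts,
and FST outlier scans — and pairs it with seeded synthetic-data generators
so every stage can be validated against a known truth.

## The four-deme divergence models

The demographic unit is a pair of ecotype pairs: four demes A1, M1, A3, M3
(alpine/montane at two localities). Backwards in time, two demes merge at
T2, the remaining two at T3, and the two ancestors merge at T1, with T1
forced to predate both. Two topologies are contrasted:

* **one origin** — the ecotypes split once: merges at T2/T3 are
  ecotype-wise (A1+A3, M1+M3), so same-ecotype demes at different
  localities are closest relatives;
* **two origins** — each locality hosts an independent ecotype split:
  merges are locality-wise (A1+M1, A3+M3).

Each topology is evaluated in strict isolation (SI, no migration) and with
continuous migration (IM). Free parameters are the four contemporary deme
sizes (diploid Ne, bounded 50–50,000 for alpine and 50–5,000 for montane
demes), the three split times (1,000–100,000 generations), the mutation
rate (1e-10–1e-8 per site per generation), and, under IM, a single
symmetric backward migration rate (1e-9–2). Ancestral deme sizes are tied
to the sum of their daughters by default; the bound 1e-9 reads the
migration prior's lower end literally. Generation time enters only when
converting generations to years for reporting and never affects inference.

Fitting is by maximum composite likelihood on the six folded joint site
frequency spectra (jSFS) of all deme pairs, treating sites as independent:
`lnCL = sum over cells of m_cell * log(p_cell)` over polymorphic cells,
monomorphic cells excluded. Expected spectra come from the package's own
structured-coalescent simulator (below); expected cell probabilities are
floored at `1/(10 * nSims)` before logging so unvisited cells do not
produce `-Inf`. Model selection uses `AIC = 2k - 2 lnCL` in natural-log
units, with `deltaL = lnCL_obs - lnCL` (distance to the saturated
multinomial) reported alongside; AIC differences are invariant to the log
base as long as one convention is fixed, and the log10 likelihood is also
stored for parity with tools that print it.

The optimizer is multi-start Nelder–Mead on logistic-transformed log10
parameters (Brent when only one parameter is free), replacing the
ECM machinery of dedicated SFS tools: for model *selection* only the
relative composite likelihoods matter, and the bounded multi-start search
recovers the generating topology reliably at desk scale. To make the
noisy Monte-Carlo objective optimizable, the simulation seed is held
fixed within a restart (common random numbers), so the objective is
deterministic given the parameters; restarts vary both the start point
and the simulation seed. T1 is parameterized as `max(T2, T3)` plus a
bounded positive excess, which enforces the ordering constraint without
penalties.

## The structured-coalescent core

The simulator (C++, exposed through `simulateGenealogies`) runs the exact
structured coalescent: k lineages in a deme of diploid size Ne coalesce at
rate `k(k-1)/(4 Ne)` per generation, each lineage migrates backward at the
model's per-pair rates, and demes merge at the event times. For every
branch segment it accumulates the segment length into a table indexed by
the per-deme counts of subtended samples. The expected jSFS is then read
off the accumulated branch lengths — a Rao-Blackwellized estimator of the
infinite-sites expectation that removes mutational noise entirely —
while realized site data (for the synthetic generator) drop Poisson
mutations on the same segments. Folding pools cell (i, j) with its
complement (n1−i, n2−j), keeping the cell whose pooled count is at most
half and splitting exact ties half-and-half; this matters for the test
suite, where the folding map is asserted cell by cell.

One numerical guard matters for fitting: each locus has a Gillespie event
budget (3,000 by default, 800 inside `fitModel`), beyond which the
remaining demes are collapsed into a single panmictic deme with the
harmonic-mean effective size — the exact strong-migration limit. Only
migration-dominated parameter proposals (backward rates approaching the
prior's upper bound, where lineages migrate thousands of times per
coalescence) ever reach the budget; for them the limit is both the
correct approximation and the difference between a millisecond and a
minute per likelihood evaluation.

Default problem sizes are desk-scale choices: 20,000 simulated genealogies
per likelihood evaluation as the package default, reduced to a few hundred
in the replicated model-recovery studies where branch-length accumulation
keeps the expectation smooth; the topology-recovery study in the test
suite uses 5,000 loci, 6 haploids per deme, 20 replicates per model class.
The IM study condition uses a weak migration rate (1e-6 per lineage per
generation): replicated divergence with strong continuous gene flow
between all demes genuinely erodes the topological signal — the data, not
the fitter, stop distinguishing the merge orders — so weak gene flow is
the regime in which topology recovery is a meaningful benchmark, and it
matches the very low migration rates the empirical system shows.

## Diversity, differentiation, outliers

Per-population summaries are the standard estimators: per-site pairwise
diversity `2 p (1-p) n/(n-1)`, Watterson's theta `S / a_n`, both divided
by the covered (variant plus invariant) sites per 50-kb window stepped by
10 kb, and Tajima's D from the 1989 constants. Differentiation uses the
Hudson estimator with the Bhatia small-sample correction,
`alpha = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` over
`p1(1-p2) + p2(1-p1)`, always accumulated as a ratio of sums — per gene,
or weighted over jSFS cells for population-level summaries; the two
accumulations agree exactly on the same data, which the tests assert. The
estimator is used throughout, including where a published pipeline might
have switched estimators between the genome-wide summary and the per-gene
scan; the choice is documented here rather than configurable.

Outlier calling flags exactly `ceiling(alpha * G)` of the G genes with
defined FST, ties at the boundary broken by gene id: this is the unique
reading of a "top 5%" rule that reproduces both printed counts in the
source system (165 of 3300 and 141 of 2811). The DEG-vs-background
permutation test compares the mean FST of a query set against means of
uniformly resampled same-size sets, two-sided around the null mean, with
the add-one correction so p is never zero.

## Differential expression

The DE stage is deliberately self-contained rather than a wrapper: genes
with mean cpm strictly above 1 (raw library sizes) are kept; TMM
normalization trims 30% of M and 5% of A values two-sided and weights by
inverse delta-method variances, with the reference sample chosen by
upper-quartile proximity to the mean; factors are rescaled to geometric
mean 1. Each gene gets a negative-binomial log-link GLM with one mean per
pair-by-ecotype cell and offsets log(effective library size). Dispersion
is estimated on a log-spaced grid by Cox–Reid adjusted profile likelihood
and moderated toward the across-gene average APL curve. The per-pair
ecotype contrast is a likelihood-ratio test against the model with that
pair's two cells merged, referred to chi-square(1), BH-adjusted per pair.

The moderation prior weight defaults to 20 residual degrees of freedom.
This was a genuinely open choice: weaker moderation (10 df) leaves enough
under-estimated dispersions in 3-replicate designs that the extreme tail
of the LRT statistic runs ahead of its chi-square reference and the
realized any-discovery rate on fully null data exceeds the nominal 5%
(measured 0.083 at 10 df vs 0.058 at 20 df over 240 null dataset-pairs).
Since the contract of this stage is calibration — the downstream
repeatability statistics consume the *sets*, so set-level error control is
what matters — the stronger moderation is the default. Exact numerical
equality with any published DE package is explicitly not a goal; edgeR
serves as an independent cross-check for the TMM factors in the tests.

log2 fold changes come from fitted cell means with a 0.5-count offset at
the mean effective library size, avoiding infinite fold changes at zero
counts. DEG sets are the eight (pair × direction) FDR < 0.05 lists over
the filtered-gene background.

## Repeatability statistics

Gene-reuse repeatability is quantified over a `GeneSetCollection` with an
explicit background: pairwise Jaccard indices and hypergeometric
upper-tail overlap tests; the analytic C-score
`(x - E)/sigma` with the hypergeometric mean `n1 n2 / N` and variance
`n1 n2 (N-n1)(N-n2) / (N^2 (N-1))` as a size-comparable effect size; a
permutation-standardized global score whose statistic is the number of
genes in at least two sets; and the exact multi-set intersection test,
computed by inclusion–exclusion over binomial moments in log space
(`P(X >= x) = sum_j (-1)^(j-x) C(j-1, x-1) B_j`), which reduces to the
hypergeometric tail at k = 2 and matches brute-force enumeration on small
universes. The alternating series monitors its own cancellation and falls
back to seeded Monte-Carlo when precision is lost; a deterministic
shortcut returns p = 1 whenever the observed intersection is at or below
the forced minimum `sum(n_i) - (k-1) N`. Category enrichment is a flat
one-sided Fisher test with BH correction — ontology DAG conditioning is
out of scope — plus the direction score `(nUp - nDown)/sqrt(nUp + nDown)`
from the log fold-change signs of the set members in each category.

Backgrounds are a deliberate choice surface: DEG statistics use all
filter-surviving genes; FST-outlier statistics use the genes with defined
FST in both scans (the intersection), mirroring how the repeatability of
selection outliers is assessed in the source system.

## Conditioned redundancy analysis

`crdaFit` implements partial RDA with one constraining variable via plain
linear algebra: centre genes, residualize both the sample-by-gene response
and the ecotype indicator on the pair indicators (the Condition step),
project the residualized response onto the residualized indicator, and
decompose. Total inertia splits exactly into conditioned + constrained +
unconstrained (asserted at 1e-9), and fractions and gene scores match
both an explicit hat-matrix oracle (1e-10) and vegan's `rda` on toy
matrices. The response is the cpm matrix by default (log2(cpm+1) is a
caller-side option). Gene scores are loadings scaled by the singular
value; only their z-transform `(score - mean)/SD` matters for outlier
calling at |z| > 2 and |z| > 2.6, which is scaling-invariant. The
permutation ANOVA permutes ecotype labels *within pair blocks* — the pair
is the nuisance stratum and the design is balanced — rather than
permuting residuals; when fewer distinct arrangements than requested
permutations exist, all of them are enumerated and the test is exact. The
constrained fraction is reported against total inertia (with the
conditioned and unconstrained fractions alongside, so the alternative
normalization against total-minus-conditioned is one division away).

## What the synthetic data do and do not emulate

`genExpression` draws log-normal gene baselines, log-normal library sizes
(median 5 million reads), and NB counts at dispersion 0.1 for the 4-pair
× 2-ecotype × 3-replicate design; DE genes receive a log2 fold change of
|N(2, 0.5)| with random sign, consistent across pairs for the shared
block. `fracShared` is the redundancy dial: the fraction of each pair's
DE genes common to all pairs; the remaining DE genes are drawn disjointly
per pair, so the planted sharing structure is known exactly and the truth
table accompanies every dataset. The generator emulates overdispersed
counts, library-size variation, and the sharing structure; it does not
emulate count correlation between co-regulated genes, composition
effects beyond TMM's reach, batch structure, or mapping artefacts — so
passing tests demonstrate calibration and power under the assumed NB
model, not robustness to those real-data features. Default desk scale is
2,000 genes (the full-data scale of ~16,000 is a parameter away).

`genGenetic` wraps the coalescent simulator: per-locus site data for the
four demes, optional per-allele miscall resampling and depth-based site
dropout (Poisson depth below a threshold), a long allele-count table and
the six folded jSFS in the `.obs` text dialect. Genotype-likelihood
machinery is upstream and out of scope; counts are taken as known.

## Numerical choices and degenerate inputs

Empty windows and S = 0 yield flagged NA, never silent zeros. Genes whose
FST denominator sums to zero are excluded from outlier ranking. Permutation
p-values use the add-one correction throughout. Composite-likelihood
probability floors, the multiset cancellation guard, and the cRDA
degenerate-score guard (zero variance of gene scores) each turn a
numerical failure mode into either an exact fallback or an explicit flag.
All stochastic operations take a mandatory seed and log it; re-running any
stage, or the whole pipeline via its manifest, reproduces outputs
byte-for-byte.

## Known limitations

Composite likelihood treats sites as independent, so linked loci inflate
confidence in model selection (only relative rankings are used here);
the coalescent core has no recombination within loci; the DE stage's
chi-square reference remains asymptotic — calibrated at the tested design
sizes, not guaranteed at n = 2; the multi-set exact test loses precision
for very large universes with large sets and then switches to Monte-Carlo;
and the pipeline's FST/DEG linkage on synthetic data is structural (the
expression and genetic gene universes are simulated independently), so
the DEG-vs-FST permutation test is exercised as a calibrated procedure,
not as a biological claim.
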