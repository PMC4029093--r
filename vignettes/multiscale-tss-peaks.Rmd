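---
title: "Multi-scale reproducible TSS peaks from CAGE data: models and methods"
author: "CAGEstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale reproducible TSS peaks from CAGE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

CAGEstack discovers transcription start site (TSS) peaks from CAGE tag
counts at every genomic scale simultaneously, scores how reproducible each
peak is across replicates, and tests the narrowest and broadest
reproducible peaks separately for differential expression. This vignette is
the package's account of the underlying models, the tunable parameters, and
the design decisions that were genuinely open.

## The clustering model

A CAGE library reduces to a CTSS table: single-nucleotide positions with
the number of tag 5' ends mapping there (`countCTSS()`, `readCTSS()`).
For one chromosome and strand, a candidate peak spanning sites $i..j$ with
tag sum $T$ is scored against a density parameter $d > 0$ as

$$S_d(i,j) = T(i,j) - d \,(\mathrm{pos}_j - \mathrm{pos}_i).$$

At a fixed $d$, the peak set is the maximal-scoring-subsequence
decomposition (Ruzzo--Tompa) of the alternating sequence of site counts and
gap penalties, trimmed to begin and end on sites. Small $d$ yields few
broad, sparse segments; large $d$ yields many short, dense ones.
`clusterSites()` returns every segment that belongs to this decomposition
for *some* $d$, annotated with the interval $[\min d, \max d)$ over which
it does. The implementation is the recursive split-at-the-weakest-boundary
algorithm: a segment's exit density is the smallest $d$ at which one of its
proper prefixes or suffixes (with the flanking gap) reaches score zero, and
the recursion descends into the two parts on either side of the (leftmost)
weakest boundary. Segments whose exit density does not exceed their entry
density never appear at any $d$ and are skipped, with their children linked
to the nearest emitted ancestor. The test suite holds this implementation
to *exact* equality with a brute-force oracle that enumerates every
critical density in rational arithmetic and runs the textbook
decomposition at each one; ties at critical densities resolve in favour of
the split (strict-inequality merging), and both routes agree on that
convention.

The emitted family is laminar: any two clusters are disjoint or nested.
Internally cluster coordinates are the 1-based inclusive positions of the
first and last site (so width is the number of covered bases and
`end - start` is the penalised extent); exported BED uses 0-based
half-open coordinates.

**Stability.** A cluster that is maximal-scoring over a wide density range
is stable: `stability = maxD / minD`. Roots (`minD = 0`) and single-site
clusters (`maxD = Inf`) have an infinite raw ratio; stability is capped at
a configurable ceiling (default 1000) before any summation so that sums
stay finite and the downstream reproducibility analysis, which consumes
ranks only, is unaffected by the choice of ceiling. **Hierarchical
stability** (`addHierStability()`) adds a cluster's stability to that of
all clusters containing it, so fine sub-peaks inherit the strength of the
promoter structure they sit in; it is the replicate-comparable score used
for reproducibility.

**Density filter.** Weak clusters are removed by normalized tag density
rather than raw tag count: clusters with TPM per base strictly below 0.1
are discarded (`densityFilter()`; a cluster exactly at 0.1 is kept). TPM
uses the per-sample total CTSS count as library size. This keeps short,
moderately expressed peaks that a raw-count cutoff would lose.

## Reproducibility: reciprocal overlap and IDR

Replicate cluster sets are merged by coordinates first: a pair matches if
the overlap covers at least 90% of both clusters (`mergeReplicates()`;
inclusive at 0.9), each cluster joins at most one pair (greedy, best
reciprocal fraction first, ties by overlap length then leftmost), and the
merged cluster keeps only the intersection. Matched pairs carry the two
hierarchical stabilities into the irreproducible discovery rate model
(`fitIDR()`): with probability $\pi_1$ a pair is drawn from a reproducible
component, a bivariate normal with mean $(\mu, \mu)$, standard deviation
$\sigma$ and correlation $\rho$; otherwise from an independent standard
bivariate normal. Observed scores enter through ranks only
(`rank / (n + 1)`, average ranks for ties), inverted through the mixture
marginal CDF to pseudo-scores.

Estimation is EM on the pseudo-scores followed by a direct likelihood
polish, and three numerical choices matter enough to spell out:

* The quantity tracked for convergence is the *copula* log-likelihood --
  the z-space mixture density divided by the marginal Jacobian. The
  uncorrected z-space pseudo-likelihood is not scale-invariant: it can be
  inflated without bound by shrinking the latent scale, and an EM guided
  by it drifts on weakly-structured data to $\pi_1 \to 1$, labelling
  everything reproducible. The corrected trace is recorded per iteration,
  is non-decreasing (the fit reverts to the best-so-far parameters if a
  step decreases it), and stops at a tolerance of `1e-4` (default;
  `idr.tol`).
* After the EM, the copula likelihood is re-maximised directly
  (box-constrained BFGS from the EM solution, the initial values, and a
  low-$\pi_1$ start) and the best solution is kept. The moment-based EM
  updates ignore the dependence of the rank inversion on the parameters
  and can stall in spike solutions on heavily tied scores; the direct
  maximisation recovers the global optimum in the cases we generate.
* The reproducible component is constrained to $\rho \ge 0.1$ (`rhoMin`),
  $\mu \ge 0$ and $\sigma \in [0.5, 10]$. Positive association is what
  *defines* reproducibility in this model; without the bound the two
  components can coincide and the labelling becomes unidentifiable on
  concordance-free data. Score pairs whose true correlation is below
  `rhoMin` are reported irreproducible, which is the conservative reading.

The local IDR of a pair is the posterior probability of the irreproducible
component; the global IDR at rank $r$ is the mean of the $r$ smallest
local IDRs -- the expected irreproducibility of the set kept at that
depth. `idrFilter()` keeps clusters with global IDR strictly below 0.1
(0.1 itself is discarded); the global flavour matches the convention of
the reproducibility tools this step emulates, and the threshold is
config-exposed. Finally `lengthFilter()` removes clusters longer than
200 bp (200 bp itself is kept). EM defaults: init
$(\pi_1, \mu, \sigma, \rho) = (0.7, 2.6, 1.3, 0.8)$, at most 200
iterations. At least 20 pairs are required; constant scores in a replicate
are a hard error. With more than two replicates the intended design is to
run every pairwise combination and report per-pair results; the pipeline
driver merges the first two replicates per condition.

## Top and bottom peaks

`buildForest()` links every surviving cluster to the smallest cluster
strictly containing it (same chromosome and strand; duplicates must be
removed first, `dedupeClusters()` keeps the higher-scoring copy). The
*bottom* peaks are the roots -- peaks contained in no other peak; the
*top* peaks are the leaves -- peaks containing no other peak; an isolated
peak is both. Extraction runs after the IDR and length filters, matching
the pipeline's step order; `buildForest()` can equally be applied to
pre-filter sets for sensitivity checks. Containment counts for size
summaries (`sizeContentTable()`) use all strictly contained clusters, not
only direct children.

## Differential expression

Counts of CTSS tags inside each tested cluster (`buildCountMatrix()`) are
compared between two conditions with a conditional negative-binomial exact
test (`nbExactTest()`), with top and bottom peaks tested as separate
matrices. Counts are equalized to the geometric-mean library size
(rounded), a single dispersion $\phi$ (variance $\mu + \phi\mu^2$) is
estimated by maximising the conditional likelihood of within-group counts
given the group sums (`estimateCommonDispersion()`; $\phi = 0$, the
Poisson limit, is an admissible boundary estimate, and a configured
default of 0.1 with a warning covers the one-replicate-per-group case),
and the p-value sums the conditional probabilities of all outcomes at most
as probable as the observed split ("small-p" rejection region). At
$\phi = 0$ this is exactly the conditional binomial test. The test suite
cross-checks both the dispersion estimate and the p-values against edgeR's
conditional-likelihood and small-p exact-test routines as an independent
reference. Multiple testing uses Benjamini--Hochberg (`bhAdjust()`); a
cluster is called significant when $|\log_2 FC| > 2$ (strict) and
adjusted $p < 0.05$ (strict). The fold change uses a prior count of 0.5
per group; "log concentration" is the log2 mean normalized abundance.
Library normalization is per-sample total CTSS count -- no trimmed-mean
step -- which is the simplest defensible choice and is config-exposed.

A gene is called differentially expressed if its promoter window (TSS
$\pm$ 500 bp, strand-matched, any $\ge$ 1 bp overlap of the whole cluster)
contains at least one significant top *or* bottom cluster
(`callDEGenes()`), and the trigger class is reported: a gene whose narrow
peak shifts while its total output is unchanged shows a significant top
with a non-significant bottom.

## The legacy comparison mode

`legacyFilter()` reproduces the classic single-scale selection: clusters
with fewer than 30 tags, raw stability below 2, or longer than 200 bp are
discarded, and only the largest surviving cluster at each site is kept.
How the original procedure combined replicates before testing is not
something the published description pins down; the pipeline applies the
same 90% reciprocal-overlap merge as the multiscale path (without the IDR
step, whose inputs the legacy filter does not produce) so that the two
modes differ exactly in the contribution under study -- multi-scale
reproducible peaks versus collapsed single-scale peaks.
`compareModes()` partitions the called genes into both/only-multiscale/
only-legacy.

## The simulator

`simulateCTSS()` generates the study conditions every test runs under: one
chromosome (1 Mb) with 40 promoters, each a broad peak of 50--200 bp
containing 1--5 sub-peaks of 1--10 bp (strictly inside, non-overlapping)
over a sparse per-base background carrying 30% of the promoter's signal at
every third base; 400 expected tags per promoter per sample; two
conditions with two replicates each. Counts are Gamma--Poisson: a
promoter-level Gamma factor (dispersion 0.15) shared by *all* samples
creates the correlated replicate scores the IDR model assumes, and an
independent per-sample Gamma factor (dispersion 0.05) creates the
between-replicate overdispersion the exact test estimates. One knob cannot
do both jobs, which is why the config carries two dispersions. 10% of
promoters are replicate-specific (emitted in a single sample -- spurious
signal that the reciprocal merge removes), background noise sites arrive
at $2 \times 10^{-5}$ per bp per sample, and among reproducible promoters
20% carry whole-promoter differential expression and 20% a sub-peak-only
shift, both at fold 8. Whole-promoter changes alternate direction by
elevating condition 1 or condition 2 symmetrically, so the expected
library sizes stay balanced -- under total-count normalization an
unbalanced design would fold the library ratio into every fold-change
estimate, which is a normalization artefact, not a property of the
methods under test. Sub-peak shifts multiply one small sub-peak (at most a
0.1 share) by the fold and scale the rest of the promoter down so the
whole-promoter expectation is exactly unchanged -- the TSS-shift
signature. The truth table records every planted interval, flag and fold.

What the simulator does *not* emulate: mapping error and multi-mapping
artefacts, sequence-composition biases, promoter shape classes
(sharp versus broad initiation profiles), chained or overlapping genes,
and genome-scale cluster counts. Passing the end-to-end checks therefore
demonstrates that the pipeline recovers planted multi-scale structure
under its own model assumptions at desk scale, not that it reproduces any
particular genome-wide figure.

## Problem sizes and numerical details

The routine test run uses: 200 random blocks of up to 12 sites for oracle
equivalence (positions up to 500, counts up to 20 -- small enough that all
critical-density arithmetic is exact in doubles); 2000 score pairs and
10 seeds for IDR recovery, 20 seeds for the shuffled null; 2000 clusters,
2 vs 2 samples and 20 seeds for exact-test calibration (cluster means
drawn uniformly from 20--200 tags, the mid-range of simulated promoter
parts); and 20 simulated datasets for end-to-end recovery. The acceptance
script repeats the same computations at slightly reduced seed counts (5-10
for the statistical summaries, 6 end-to-end datasets). These sizes were
chosen as the smallest at which the stochastic checks are stable.

Remaining numerical conventions: break-density ties in the clustering
recursion split at the leftmost minimising boundary; equalized counts are
rounded to integers before the conditional test; the exact test treats
outcome probabilities within a relative `1e-10` of the observed one as
ties (so symmetric cases include both tails exactly); promoter windows are
clipped at position 1; and every file the pipeline writes is plain text
with deterministic formatting, so a fixed seed reproduces runs byte for
byte.

## Known limitations

* The IDR fit is a two-component Gaussian copula; heavily discretised
  scores (many ties) weaken it, and the `rhoMin` constraint deliberately
  reports weakly-correlated replicates as irreproducible rather than
  guessing.
* The common-dispersion model shares one $\phi$ across clusters;
  cluster-wise or trended dispersion is out of scope.
* The pipeline driver consumes exactly two conditions and merges the
  first two replicates per condition; all-pairs replicate designs are
  supported at the function level (`mergeReplicates()` on any pair).
* Containment forests on merged (intersection) clusters can contain
  partially overlapping intervals; such pairs share no edge, which can
  make a gene's "bottom" peak a set of intervals rather than a single
  root.
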