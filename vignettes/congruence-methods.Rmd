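---
title: "Testing host-virus phylogenetic congruence: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing host-virus phylogenetic congruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cophylotest)
```

## The question

A strictly vertically transmitted symbiont should cospeciate with its
host: its gene tree, restricted to the symbiont taxa and relabelled with
their hosts, should equal the host species tree. `cophylotest` asks
whether sequence data reject that mirror-image hypothesis, using three
statistics of different character: a likelihood test (SH), an exact
Bayesian topology count, and a distance-based similarity null. The three
are deliberately complementary — the SH test asks *is the constrained tree
significantly worse*, the posterior match asks *does the data ever favour
the host topology*, and the RF null asks *is the virus tree closer to the
host tree than chance even when not identical* (partial congruence, e.g.
from preferential switching between related hosts).

## Sequence model

All likelihoods use the general time-reversible family. The rate matrix is
built from six exchangeabilities $s_{ij}$ (order AC, AG, AT, CG, CT, GT;
GT is the reference and is fixed at 1) and stationary frequencies $\pi$:
$q_{ij} = s_{ij}\pi_j$, diagonal such that rows sum to zero, and the whole
matrix scaled so $-\sum_i \pi_i q_{ii} = 1$ — branch lengths are expected
substitutions per site at stationarity.

Among-site rate variation uses the discrete-gamma convention: $k = 4$
equal-probability categories of a mean-1 gamma with shape $\alpha$, each
represented by its conditional mean. With a proportion $p_{inv}$ of
invariable sites the per-site likelihood is

$$L_s = p_{inv}\,\pi_x\,[\text{site constant at } x]
      + (1 - p_{inv})\,\tfrac1k \sum_c L_s(r_c).$$

One convention point deserves emphasis: **the gamma mean stays 1 when
$p_{inv} > 0$** — the variable fraction is *not* rescaled by
$1/(1-p_{inv})$. Some widely used implementations rescale; the two
conventions describe identical models with branch lengths differing by the
factor $1-p_{inv}$, and the test suite verifies this correspondence
against an independent implementation exactly. Comparisons of branch
lengths across software must account for it.

Likelihood evaluation is Felsenstein pruning over compressed site
patterns, in C++, with per-node rescaling of partial vectors and log-space
accumulation of the scale factors: divergent alignments of a few kilobases
underflow double precision without it. Ambiguity codes contribute partial
vectors with ones at compatible states; `-`, `N` and `?` are
fully missing. Per-site log-likelihoods are reported for every original
column (the RELL resampling unit), whatever the internal compression.

## Inference machinery

**Branch lengths** are optimized coordinate-wise by Brent's method,
sweeping all edges until the log-likelihood gains less than $10^{-6}$ per
sweep. **Model parameters** are optimized on transformed scales (log
rates, log-ratio frequencies, log $\alpha$, logit $p_{inv}$) by
Nelder-Mead (Brent when the family has a single free parameter),
interleaved with branch sweeps. The interleaved profile over the
$\alpha$/$p_{inv}$ ridge is notoriously flat; convergence is declared at
$10^{-3}$ log-likelihood units between rounds, which changes no downstream
statistic while avoiding a long crawl along the ridge.

**Tree search** is best-improvement NNI hill-climbing from a
neighbour-joining start on Jukes-Cantor distances: all rearrangements of
every internal edge are scored with a quick re-optimization of the five
branches around the swap, the best improving move is accepted and followed
by a full sweep, until no move improves. **Model selection** fits each
candidate family on the fixed topology and ranks by $AIC = 2K - 2\ln L$
with $K$ counting branch lengths plus free model parameters; ties break
toward fewer parameters so the result is order-invariant. The default
ladder is the 16 members JC/K80/HKY/GTR $\times$ {plain, +Γ, +I, +Γ+I};
the historical 56-model ladder adds nothing here since only the selected
family feeds the downstream tests. **Bootstrap** replicates restart the
search from the ML tree — a cost-motivated and standard choice that can
only make supports conservative for splits the ML tree lacks.

**MCMC.** The Bayesian sampler is a single Metropolis-Hastings chain over
(topology, branch lengths, model parameters): NNI moves on a uniformly
chosen internal edge (symmetric, since every unrooted binary topology has
$2(n-3)$ NNI neighbours), a single-branch multiplier (Hastings ratio
$t'/t$), reflected sliding windows on $\alpha$ and $p_{inv}$, and
Dirichlet proposals centred on the current frequencies/exchangeabilities.
Priors: exponential (mean 0.1) on branch lengths, exponential (mean 1) on
$\alpha$, uniform on $p_{inv}$, flat Dirichlet on $\pi$ and on the
exchangeability simplex. The chain is single (no Metropolis coupling):
desk-scale alignments mix adequately with NNI proposals, and the
congruence tests only consume the topology sample. A split-frequency
diagnostic compares the two halves of the post-burn-in sample and warns
above a discrepancy of 0.05. The reference run profile is $10^6$
generations sampled every 100 with 25% burn-in; scaled-down runs
(50,000 generations sampled every 50) give indistinguishable topology
proportions on the shipped fixtures and are the default for the suite
runner.

## The three congruence tests

**Topology comparison is unrooted throughout.** Outgroup-based rooting is
display information; the congruence claim concerns the ingroup
arrangement, and the outgroups are pruned before comparison anyway.
Comparison operates on canonical bipartitions (the split side not
containing the lexicographically smallest leaf), trivial splits excluded;
the Robinson-Foulds distance is the raw symmetric-difference count (the
normalized variant is exposed separately).

**SH test.** The candidate set is exactly {ML tree, host-constrained
tree}. The constrained tree rearranges the mapped leaves to mirror the
host topology, grafted at the attachment point of the lexicographically
smallest mapped leaf, leaving unmapped taxa in their ML arrangement; its
branch lengths are re-optimized under the ML model. RELL resampling
(default 1000 replicates) draws site columns with replacement, centres
each topology's replicate sums by their own mean, and takes the
max-over-topologies centred value minus the topology's centred value as
the replicate statistic — the full multi-topology recipe, retained even
with two candidates so p-values match general conventions.

**Posterior matching** counts exact unrooted matches after
`map_and_prune`. It needs no tolerance: RF distance is integer-valued.

**RF null.** "Closer than the posterior sample" is operationalized as
*closer than the mean posterior RF distance*; the median variant is
computed and reported alongside (both appear in every report), since
either reading is defensible and they can differ when the posterior is
multimodal. Null topologies are uniform over labelled unrooted binary
topologies via sequential random attachment — the maximal-entropy choice
when no shape model is stated; a Yule-shaped null would concentrate on
balanced trees and make the test less conservative.

## The synthetic-data generator

Host trees are Yule: waiting times $\mathrm{Exp}(k\lambda)$ while $k$
lineages exist, uniform choice of splitting lineage, plus a final
$\mathrm{Exp}(n\lambda)$ stem to the present. The stem is a deliberate
addition: without it the last speciation sits exactly at the present and
two tips carry zero-length branches, making part of every fixture
unresolvable in principle. With it, $E[\text{height}] = \sum_{k=2}^{n}
1/(k\lambda)$, which the tests check against simulation.

Virus trees copy the host tree, scale branch lengths by
`virus_rate_scale` (time → substitutions/site), and apply `n_switches`
subtree-prune-regraft moves with uniformly chosen pruned subtree and
regraft edge; the edge freed by the prune is excluded as a target, so
every switch changes the topology. Host switches are topology-only events
here — no timing model, no extinction — because the congruence tests
consume topology alone. Alignments are evolved site by site: invariable
with probability $p_{inv}$, otherwise a gamma category, root state from
$\pi$, transitions down the tree from the model's $P(t r_c)$ matrices.

Fixture defaults, chosen once as a realistic regime for a divergent viral
polymerase gene and then left alone: 8 taxa, $L = 2000$, `yule_rate` 1,
`virus_rate_scale` 0.3 (root-to-tip roughly 0.3-0.5 substitutions/site,
matching the deep divergence among sigma-virus RDRP sequences),
exchangeabilities (1.5, 4.0, 0.9, 1.1, 4.5, 1) — transitions about four
times transversions — frequencies (0.30, 0.20, 0.20, 0.30), $\alpha=0.5$,
$p_{inv}=0.1$.

What the generator does *not* emulate: alignment error and trimming,
compositional heterogeneity across lineages, rate variation specific to
individual virus branches (a multiplier-noise option exists but defaults
to off), recombination, and within-host diversity. Passing tests
demonstrate the pipeline's correctness and calibration *under the model*;
they do not certify behaviour under systematic misspecification of these
kinds.

## Numerical choices and degenerate inputs

* Brent per-edge tolerance $10^{-9}$ (down to $10^{-11}$ where closed-form
  comparisons demand it); branch-length bracket $[10^{-9}, 10]$
  substitutions/site.
* Eigendecomposition of the $\pi$-symmetrized rate matrix for
  $P(t)=e^{Qt}$; tiny negative entries from round-off are clamped to zero.
* Site-pattern compression keys on column tuples; zero-length alignments
  are legal and give $\ln L = 0$ (used to verify the samplers against
  their priors).
* Trees with fewer than four leaves have no non-trivial splits: RF is 0
  and `bipartition_set` returns the empty set rather than erroring.
* Polytomies are accepted by the comparison machinery (their fewer splits
  are simply counted); the generators and the search only produce binary
  trees.
* NNI on the flat posterior is exactly symmetric, which the test suite
  checks by chi-square against the uniform distribution over quartet
  topologies.

## Scaled-down study sizes

The calibration studies run at sizes chosen to make the full suite a
matter of minutes on a single core while keeping every binomial bound
meaningful: 40 cospeciation replicates for the SH type-I check (size
$\le$ 10% at $\alpha=0.05$, reflecting SH's conservatism), 20 three-switch
replicates for power (significant in $\ge$ 16/20, posterior match exactly
0 in 20/20), posterior sampling at 50,000 generations for the shipped
fixture and 8,000 for the replicate study, and $10^4$ random topologies
for the RF null (matched against exhaustive enumeration of all 945
seven-leaf topologies).

## Known limitations

* The MCMC is single-chain; for hard posteriors (large trees, conflicting
  signal) Metropolis-coupled chains would mix better. The split-frequency
  warning is the guard rail.
* SH with RELL re-optimizes nothing per replicate; with very short
  alignments the approximation to full optimization degrades.
* The constrained-tree construction grafts the host-shaped subtree at a
  single anchor; when mapped taxa are deeply paraphyletic in the ML tree
  there are other defensible placements, all sharing the defining
  invariant (the induced topology on mapped taxa equals the host tree).
* A posterior that genuinely concentrates on the true topology still
  carries a few per cent mass on its NNI neighbours at $L = 2000$; exact
  statements like "no random topology is closer" should be read with that
  in mind.
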