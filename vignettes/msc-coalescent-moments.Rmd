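---
title: "Exact moments of pairwise coalescence times and the bias of sequence-based F_ST"
author: "msccov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact moments of pairwise coalescence times and the bias of sequence-based F_ST}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msccov)
```

## The model

`msccov` works under the multi-species coalescent (MSC): a Kingman
coalescent run inside each branch of a rooted, strictly bifurcating species
tree.  Time is measured in generations and increases into the past; tips
sit at time 0.  Every branch carries an ordered list of *epochs* — half-open
intervals $[\tau_k, \tau_{k+1})$ with constant diploid population size
$\eta_k$ — so any piecewise-constant demography can be expressed.  Within an
epoch, each pair of lineages resident in that population coalesces at rate
$1/(2\eta_k)$ per generation.  Lineages in different populations cannot
coalesce until the populations share an ancestor: there is no migration,
introgression or admixture in the model, which is exactly the constraint
that every coalescence is at least as old as the corresponding species
divergence.

Three layers are built on this process:

1. **Coalescence times.**  For one pair of lineages, the *marginal profile*
   of the pair's shared ancestral path (a piecewise-constant size history on
   $[t_0,\infty)$) gives the density of the coalescence time $t$ in closed
   form, and hence $E(t)$, $E(t^2)$ and $\mathrm{Var}(t)$.  For two pairs
   drawn from up to four sampled lineages, the engine computes the exact
   product moment $E(t_A t_B)$, the covariance, the distribution over the
   six possible orderings of the two pairs' MRCA events, and the expected
   *shared branch length* $E(t_\cap)$ — the expected total length of
   gene-tree edges lying on both pairs' connecting paths.

2. **Pairwise sequence differences.**  Under infinite sites with no
   recombination, the difference count of a pair is Poisson with mean
   $2\mu t$ conditional on the gene tree ($\mu$ is the mutation rate per
   sequence per generation).  The laws of total variance and covariance
   give
   $\mathrm{Var}(k) = 2\mu E(t) + 4\mu^2\mathrm{Var}(t)$ and
   $\mathrm{Cov}(k_A, k_B) = \mu E(t_\cap) + 4\mu^2\mathrm{Cov}(t_A,t_B)$:
   conditional on the tree, the covariance of two difference counts is the
   mutation rate times their shared branch length.  Averaging over the
   $\binom{n_X}{2}$, $\binom{n_Y}{2}$ and $n_X n_Y$ pairs yields the exact
   means, variances and covariances of $d_X$, $d_Y$, $d_{XY}$ and the net
   divergence $d = d_{XY} - (d_X + d_Y)/2$.

3. **F_ST.**  The coalescent fixation index of two populations is
   $F_{ST} = 1 - \tfrac12\,(E(t_{XX}) + E(t_{YY}))/E(t_{XY})$, a pure
   function of mean coalescence times.  Its single-locus plug-in estimator
   $F_{ST}^G = (d_{XY} - \tfrac12(d_X + d_Y))/d_{XY}$ is a ratio of
   correlated random averages and is therefore biased; `msccov`
   approximates its expectation, bias and variance, and the induced bias of
   the island-model gene-flow transform
   $\langle Nm\rangle_F = (1/F_{ST} - 1)/2$ and of two divergence-time
   linearizations, by delta-method (Taylor) expansions evaluated at the
   *exact* moments from layer 2.

## The exact engine

### Pair moments

`pair_time_moments()` integrates $t$ and $t^2$ against the coalescence
density interval by interval over the marginal profile.  Each interval
contributes a scalar closed form weighted by the probability that the pair
failed to coalesce in all earlier intervals (the "two-in, two-out" survival
probability, `survival_prob()`, a product of $e^{-\Delta_k/2\eta_k}$
factors); the unbounded root epoch uses the closed form's limit.  Short
intervals relative to $2\eta$ would suffer cancellation in the naive
$\text{const} - (\cdot)e^{-x}$ arrangement, so the terms are rearranged
around `expm1()`.

### Joint moments: the ancestral-configuration chain

Joint quantities need the full combinatorics of event orderings along the
tree.  Rather than enumerating ordered topology cases by hand, the engine
tracks the *labelled ancestral-lineage configuration*: the state is the set
partition of the 2–4 sampled lineages into ancestral lineages (at most 15
states).  A block's location at time $t$ is determined by its members'
populations and the species tree, so between two consecutive "segment"
boundaries (the union of divergence times and epoch boundaries) the process
is a continuous-time Markov chain with a constant generator whose merge
rates are $1/(2\eta)$ for each pair of blocks resident in the same
population.  All target quantities are integrals of this chain and are
evaluated without quadrature:

* $E(t_\cap)$ integrates the expected number of blocks subtending exactly
  one member of each pair; per segment this is
  $p^\top\!\big(\int_0^L e^{Qu}\,du\big) n$, with the integral obtained as a
  block of a single matrix exponential (Van Loan's construction) and the
  root epoch contributing $p^\top(-Q_T)^{-1} n_T$ in phase-type form.
* $E(t_A t_B)$ is written as
  $\int_0^\infty E\{\mathbf 1[t_A > t]\, m_B(X_t, t)\}\,dt$ plus the
  symmetric term, where $m_B$ is the mean residual time to pair B's
  coalescence.  The $m$ vectors are propagated backwards through the
  segments; the forward sub-probability over "both pairs uncoalesced"
  states is combined with them through two- and three-block Van Loan
  exponentials.
* The ordering probabilities $C_1\ldots C_6$ (pair A's MRCA first; second
  with B's third; both simultaneously at the final event; B's second with
  A's third; B's first with A's second; B's first with A's third) come from
  a small augmented chain that records at which coalescent event each
  pair's MRCA occurred.  The simultaneous case $C_3$ — a single event
  completing both pairs — is its own absorbing class, never approximated by
  a tie-break perturbation.

Matrix exponentials (Padé scaling-and-squaring via the Matrix package) are
exact to machine precision, like `exp()` itself; there is no tolerance knob
anywhere in the engine.  Degenerate inputs reduce exactly: identical pairs
return the pair's second moment with $t_\cap = 2 t_A$ and $P(C_3)=1$;
three-lineage configurations are the four-lineage machinery after
identifying two labels.  The test suite pins the engine to independently
derived staged-exponential constants (panmictic covariances $1/3$ and $2/9$
and shared branch lengths $1$ and $2/3$ in $2\eta$ units, to $10^{-10}$)
and to Monte Carlo estimates on species-tree scenarios.

### Numerical and convention choices

* Epochs are half-open $[\tau,\tau_{p})$; at a divergence time the lineage
  is already in the parent population.
* A divergence time of 0 is allowed (the tip branches have zero length and
  carry no epochs), giving an effectively panmictic pair of tips; this is
  the natural limit of the divergence grid and is used by the validation
  sweeps.
* Zero-length epochs are dropped and adjacent equal-size epochs merged at
  parse time, so serialization is canonical and `parse(serialize(S))` is
  the identity.
* Internal units are generations and diploid sizes.  Configs may instead
  declare `time_units = "2N_ref"` with a reference size `N_ref`; times are
  multiplied by $2N_{\mathrm{ref}}$ and sizes by $N_{\mathrm{ref}}$ at
  parse time, matching the common scaled presentation
  ($D' = D/2\eta_X$, sizes as multiples of a reference).

## The Taylor layer

All estimator approximations are evaluated at the exact difference-statistic
moments — never at simulated ones — so that the approximation error being
studied is not confounded with sampling error.  `e_fstg_approx()` is the
standard second-order expansion of $E(A/B)$,
$E(A)/E(B) + E(A)\mathrm{Var}(B)/E(B)^3 - \mathrm{Cov}(A,B)/E(B)^2$, with
$A = d_X + d_Y$, $B = d_{XY}$; `e_nm_approx()` applies the same expansion
with $B = d$ (the net divergence); `var_fstg_approx()` is the first-order
delta-method variance.  The variance approximation is known to degrade at
recent divergence times, where higher-order terms matter; its return value
carries a permanent `low_trust` attribute, and the package's own validation
only checks it in the deep-divergence regime.  The log-linearization
$-\log(1-F_{ST}^G)$ is propagated at first order only (no trustworthy
variance is available to do better); the ratio linearization
$F_{ST}^G/(1-F_{ST}^G)$ uses a second-order expansion of
$E(d_{XY}/(d_X+d_Y))$.

Two structural facts fall out exactly and are asserted in the tests: with
equal constant sizes, $F_{ST} = D'/(D'+1)$ and $F_{ST}/(1-F_{ST}) = D'$
(the ratio transform is exactly linear in the divergence time); and the
estimator's expectation approximation reduces to $F_{ST}$ whenever all
variance and covariance terms vanish.

## The simulator and what passing tests mean

`simulate_gene_trees()` is a direct event-driven MSC simulator: within each
branch segment, the $m$ resident lineages coalesce after exponential
waiting times of rate $\binom m2/(2\eta)$, truncated at segment boundaries;
survivors are handed to the parent population and the root runs to
completion.  `overlay_mutations()` draws Poisson counts per gene-tree edge
and sums them along paths, so pairwise counts are marginally
$\mathrm{Poisson}(2\mu t)$ while preserving the shared-branch covariance
structure.  The simulator emulates exactly the model the theory assumes —
infinite sites, no recombination, no migration, free of ascertainment — so
agreement between engine and simulator validates the mathematics, not the
fit of the model to real data.  Real sequence data additionally have finite
sites (recurrent mutation saturates differences at high $2\mu\eta$),
recombination (which shrinks the variance of the averaged statistics), and
error processes; none of these are represented, and conclusions about the
magnitude of estimator bias transfer to data only as far as those
assumptions do.

Validation sizes are chosen to make a 4-standard-error criterion sharp but
cheap: 50,000 replicate gene trees for the time-moment sweeps (two size
scenarios $\eta_Y \in \{1,2\}\eta_X$ across a divergence grid of 0–20 in
$2\eta_X$ units, every mean, variance and covariance class among 3+3
lineages) and 1,500 infinite-sites loci for the nine difference-statistic
scenarios ($\eta_Y \in \{1,2,10\}\eta_X \times 2\mu\eta_X \in
\{10,1,0.1\}$, $n_X=n_Y=10$).  Seeds are fixed in the tests; the simulator
consumes R's RNG sequentially from a single `set.seed()` per call, so a
batch is bit-reproducible given `(seed, R)`.

A deliberate policy decision: per-locus $F_{ST}^G$ is undefined when a
locus has $d_{XY}=0$ (common at low mutation rates).  `empirical_fst()`
excludes such loci from the per-locus mean and reports their count loudly
(`n_excluded`), while the multi-locus ratio-of-averages estimate uses all
loci.  Exclusion is the only self-consistent choice for a per-locus ratio,
but it is itself a selection effect at low $2\mu\eta$ — one more reason the
per-locus mean should not be over-interpreted there.

## Bottleneck presets

`bottleneck_tree()` encodes four two-population scenarios with equal
baseline size $\eta_0$: no bottleneck; a 10-fold size reduction in X
starting at the present ("recent"); the same reduction ending at the
divergence ("postsplit"); and a reduction in the ancestral population
starting at the divergence ("ancestral").  Bottlenecks on the X branch last
$\min(1, D')\,2\eta_0$ generations so that they always fit on the branch —
for $D' \le 1$ the recent and post-split histories coincide — and the
ancestral bottleneck lasts $2\eta_0$ generations.  The exact engine shows
the recent bottleneck raising $F_{ST}$ at every divergence (it shortens
within-X coalescence times while between-population times are dominated by
$D$), while the effect of older bottlenecks washes out with time since the
bottleneck.

## Known limitations

* Joint moments cover two pairs (up to four lineages); no third or higher
  moments, and no joint distributions over more than two pairs.
* Difference statistics are developed for two populations; the species-tree
  machinery itself handles arbitrarily many tips.
* No migration, recombination, growth curves (only piecewise-constant
  sizes), or finite-sites mutation.
* The variance approximation for the estimator, and everything downstream
  of it, is first order and untrustworthy at recent divergence — flagged,
  not fixed.

## A worked example

```{r example, eval = FALSE}
S <- two_pop_tree(D = 20000, eta_x = 10000)  # D' = 1 in 2*eta units
fst_true(S, "X", "Y")                        # 0.5 exactly
rep <- fst_report(S, mu = 0.1 / (2 * 10000), nX = 10, nY = 10)
rep                                          # bias, <Nm>_F, linearizations
```
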