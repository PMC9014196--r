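# msccov

Exact moments of pairwise coalescence times under the multi-species
coalescent (MSC), and what they imply for sequence-based **F_ST**.

Population geneticists routinely summarize divergence between two
populations X and Y through average pairwise sequence differences — d_X and
d_Y within populations, d_XY between them, and the net divergence
d = d_XY − (d_X + d_Y)/2 — and through Slatkin's coalescent fixation index

    F_ST = 1 − (E t_XX + E t_YY) / (2 E t_XY),

estimated from a single non-recombining locus as
F_ST^G = (d_XY − (d_X + d_Y)/2) / d_XY.  Because the d statistics are
*correlated* averages over one shared gene tree, F_ST^G is a ratio of
dependent random variables and is biased.  Quantifying that bias requires
the full second-moment structure of pairwise coalescence times on a species
tree: not just E(t) and Var(t) for each pair, but Cov(t_A, t_B) for any two
pairs of lineages, and the expected *shared branch length* E(t∩) that
couples their mutation counts (Cov(k_A, k_B | tree) = μ·t∩).

`msccov` computes all of these **exactly** on any rooted bifurcating
species tree with piecewise-constant diploid population sizes and no
post-divergence gene flow, by tracking the labelled ancestral-lineage
configuration (a set-partition Markov chain) through the tree's epochs,
with every integral evaluated in closed form or as a matrix-exponential
block — no quadrature, no simulation in the exact path.  On top of the
time layer it provides:

* infinite-sites moments of d_X, d_Y, d_XY, d for arbitrary sample sizes
  (n_X, n_Y) and mutation rate μ (per sequence per generation);
* delta-method approximations for E(F_ST^G), its bias and variance, the
  island-model gene-flow transform ⟨Nm⟩_F = (1/F_ST − 1)/2, and the
  −log(1−F) and F/(1−F) divergence-time linearizations;
* bottleneck scenario presets (recent / post-split / ancestral 10×
  reductions) for studying how bottleneck timing moves F_ST;
* a seeded Monte Carlo MSC gene-tree simulator with infinite-sites mutation
  overlay (`simulate_gene_trees()`, `overlay_mutations()`), used throughout
  the test suite as an independent oracle for every exact quantity;
* a JSON-config command-line front end (`inst/cli/msccov`) with
  `moments`, `diffstats`, `fst`, `simulate` and `validate` subcommands.

## Worked example

A two-population tree with divergence D = 20,000 generations and constant
diploid sizes η = 10,000 everywhere (so D′ = D/2η = 1), sampled at
n_X = n_Y = 10 with composite mutation rate 2μη = 0.1:

```r
library(msccov)
S <- two_pop_tree(D = 20000, eta_x = 10000)
fst_true(S, "X", "Y")
#> [1] 0.5
fst_report(S, mu = 0.1 / (2 * 10000), nX = 10, nY = 10)
#> F_ST report (mu = 5e-06, nX = 10, nY = 10):
#>   F_ST (true)        0.5
#>   E(F_ST^G) approx   0.200115   bias -0.299885
#>   Var(F_ST^G) approx 0.227461   (first order; low trust at small D)
#>   <Nm>_F true 0.5   E approx 2.00961   (+302%)
#>   linearizations: -log(1-F) 0.223287   F/(1-F) 1.62015
```

With equal sizes F_ST = D′/(D′+1) exactly, hence 0.5 here.  The report
shows the single-locus estimator expecting only ≈ 0.20 at this low mutation
rate — a strong downward bias that would, plugged into the gene-flow
transform, *overestimate* ⟨Nm⟩_F fourfold (0.5 → 2.01).  The underlying
exact time moments are available directly:

```r
pair_time_moments(S, "X", "Y")
#> pair coalescence time: mean 40000  var 4e+08  (E t^2 = 2e+09)
cfg <- sample_config(c(i1 = "X", i2 = "X", j1 = "Y", j2 = "Y"),
                     pairA = c("i1", "i2"), pairB = c("j1", "j2"))
joint_pair_moment(S, cfg)
#> joint coalescence-time result:
#>   E(tA tB) = 4.1203e+08   Cov = 1.20298e+07   E(t_cap) = 1804.47
#>   case probabilities: C1=0.4549 C2=0.03007 C3=0.03007 C4=0.03007 C5=0.2848 C6=0.1701
```

Every such number is validated in the test suite against a 50,000-replicate
Monte Carlo run of the built-in simulator (4 standard-error criterion) and,
for the panmictic limit, against independently derived closed-form
constants to 1e−10.

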