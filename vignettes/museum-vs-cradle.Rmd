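---
title: "Methods: delimiting species and testing museum versus cradle diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delimiting species and testing museum versus cradle diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(museumdiv)
```

This vignette documents the models behind `museumdiv`, the conventions and
numerical choices baked into the code, what the synthetic-data generators do
and do not emulate, and the package's known limitations. Time is always
measured backward from the present: tips sit at age 0 and ages grow toward
the root. Chronogram ages may be absolute (Ma) or relative (root scaled to
1); every statistic here is either invariant to, or explicitly conditioned
on, that scale.

## Mean-path-length dating

`mpl_ultrametricize()` assigns each internal node the mean, over its
descendant tips, of the node-to-tip path length (its MPL), then rescales so
the root equals `root_age` (default 1, the convention used when a relative
chronogram feeds GMYC delimitation). The MPL estimator assumes rate
variation averages out across a node's descendants; under strong, clade-wide
rate shifts a child's MPL can exceed its parent's. Such conflicts are
repaired tips-to-root by lifting the parent to the child's age plus `delta`
(default 1e-9, i.e. the minimal monotone repair). We chose minimal repair
over redistributing the discrepancy across neighbouring nodes because it
perturbs only the nodes actually in conflict; the output is ultrametric by
construction either way. Multiplying all input branch lengths by a positive
constant leaves the relative ages unchanged.

`clock_test()` compares, at each internal node, the MPLs of the two child
subtrees with a z-statistic. The variance comes from treating each branch's
substitution count as Poisson (variance equal to its expectation) and
propagating through the MPL recursion: a branch subtending `w` of the
subtree's tips contributes `w^2 * length` to the variance of the path sum.
An alternative would be to estimate the variance empirically from the spread
of root-to-tip path lengths, but paths within a subtree share branches, so
that estimator ignores most of the true sampling variance and rejects far
too often on clock-like data; the Poisson form is calibrated (per-node
type-I error tracks the nominal level in the test suite's simulations, which
generate Poisson branch counts on Yule trees). When branch lengths are in
substitutions per site rather than counts, pass the alignment length as
`sites`; the statistic scales with its square root. The tree-wide verdict
applies a Bonferroni correction over tested nodes at `alpha = 0.05`.

## GMYC single-threshold species delimitation

The single-threshold GMYC model places a threshold age `T` on an ultrametric
single-locus tree. Events older than `T` belong to a diversification (Yule
type) process; branches crossing `T` define entities (putative species), and
events younger than `T` are coalescences within their entity. Within each
inter-event interval `i` of duration `x_i` the branching intensity is

    b_i = lambda1 * n_d^p1 + lambda2 * sum_j [n_j (n_j - 1)]^p2

where `n_d` counts diversification lineages (the actual lineage count above
`T`; the constant number of entities below it) and `n_j` counts the lineages
of cluster `j` crossing the interval. The likelihood treats the ordered
branching ages as a single point process: `prod_i b_i exp(-b_i x_i)`, with
pure waiting terms for the two intervals cut by `T` or ending at the
present. The crown split is conditioned on (no event term), so the mixed
model and the null share `n - 2` event terms. We considered the alternative
of crediting each event only its own component's rate (a labeled-
superposition likelihood); it penalizes a k-cluster threshold by roughly
`log k` per coalescent event relative to single-process fits, destroying the
threshold's identifiability in simulation, and it is not the form under
which the classical single-threshold method behaves as published. The
point-process mixture is therefore the implemented likelihood.

The null model is a single process with intensity
`lambda * [n(n-1)]^p` over the whole tree (two free parameters). Because a
threshold candidate above the crown reduces the mixture to exactly this
form, the maximized mixed likelihood can never fall below the null, and
`2 * (logL_gmyc - logL_null)` is referred to chi-square with 3 degrees of
freedom (five versus two parameters), the convention of the original method.
The chi-square reference is asymptotic: on very small trees (roughly 15 tips
or fewer) the test runs conservative in our simulations; at 25 or more tips
the type-I error tracks the nominal 5%.

Numerical choices: candidate thresholds are the midpoints between
consecutive distinct node ages plus three boundary candidates (above the
crown = one entity; below the youngest node; exactly 0 = every tip an
entity). At each threshold the four free parameters are maximized by
bounded L-BFGS-B on (log lambda1, log lambda2, p1, p2) with rate bounds
[1e-8, 1e6], exponent bounds [0, 5], and three starts seeded from the
events-per-tree-length scale; a threshold whose optimization fails is
skipped with a warning. Among equal-likelihood thresholds the one with the
fewest entities wins — conservative splitting, consistent with retaining
described names unless the data demand more entities. (Note the opposite
reading, "most recent threshold", would maximize the entity count; the two
cannot coincide.) The confidence set reports every scanned threshold within
2 log-likelihood units of the optimum and the implied entity-count range.

`consensus_reduce()` collapses each cluster's aligned sequences column by
column: unanimous base (gaps and Ns ignored), otherwise the IUPAC code of
the observed bases, all-gap columns staying gaps.

## Time-stratified DEC

Ranges are non-empty subsets of the area list with at most `maxareas` areas
(default 2; 22 states for six areas including the absorbing null range, 42
at `maxareas = 3`), minus any ranges excluded as biologically implausible.
Along a branch, area `b` is gained at rate `d * sum_{a in R} m_s[a, b]`
(additive source contributions, with `m_s` the slice's scaling matrix) and
each occupied area is lost at rate `e`; the empty range is absorbing. A
branch spanning slice boundaries multiplies segment exponentials oldest
first; times older than the oldest boundary reuse slice 1's matrix. Matrix
exponentials use a cached eigendecomposition per slice, accepted only when
it reconstructs the rate matrix to 1e-9, with a scaling-and-squaring
fallback otherwise — the state space here is at most tens of states, so
dense linear algebra suffices.

At a node, a single-area range is inherited by both daughters; a wider range
splits by vicariance (one daughter gets one area, the other the remainder)
or subset sympatry (one daughter gets one area, the other the full range),
with ordered daughter scenarios weighted uniformly per ancestral range. The
root constraint "origin in area A" is implemented as the root range fixed to
exactly {A} (`root_range = "A"`); passing `NULL` averages over permitted
ranges under a flat prior. Fixed-state is the conventional reading of a
root-area constraint; a contains-A variant can be emulated by summing fixed
roots over the ranges containing A.

`dec_optimize()` maximizes over (d, e) on the log scale with bounds
[1e-9, 10] and relative tolerance 1e-7, then scores every (range,
daughter-scenario) candidate at every internal node by an outside pass, so
each candidate's value is the *global* likelihood with that reconstruction
fixed. Candidates within 2 log-likelihood units of a node's best are
reported — the conventional significance rule for ancestral ranges. A rate
estimate pinned at a bound raises a flat-likelihood warning; with extant
ranges only, `e` is weakly identified and commonly sits at the lower bound
even when the generating extinction rate was positive, which is a known
property of DEC-type inference rather than an optimizer artifact. The
`maxareas = 2` and `maxareas = 3` spaces are not nested models, so their
optimized likelihoods need not be ordered; the package's tests assert close
agreement of fits and reconstructions instead.

## Diversification battery

`gamma_stat()` implements the standard constant-rates statistic from
internode intervals; its one-tailed p-value is the standard normal CDF at
the observed value (small values = early-concentrated branching). The MCCR
test corrects for incomplete sampling: `mccr_test()` simulates complete
pure-birth trees at the true richness `n_total`, prunes each uniformly at
random to `n_sampled` tips, and reports the 5th percentile of the null γ
and the fraction of null values at or below the observed γ. The simulation
rate is fixed at 1 because γ is invariant to time rescaling. The null
simulator draws independent internode intervals `g_k ~ Exp(k λ)` for
`k = 2..n` (the memoryless "observed now" conditioning) with uniform
lineage splitting: this is the exact null under which γ is standard normal,
and the complete-sampling critical value converges to −1.645.

All Yule-family model fits share one conditioning convention: the crown
split is given, so `n - 2` branching events carry log-rate terms, and the
waiting normalizer is `sum_k k * lambda(k) * g_k` over all intervals
including the open one at the present. Under this convention the pure-birth
MLE is `lambda = (n-2) / sum k g_k` in closed form, and the birth-death
model (parameters: net rate and relative extinction) reduces to it exactly
at zero extinction. The rate-variable set comprises density-dependent
logistic (`DDL`, `lambda(N) = r (1 - N/K)`, K bounded above the tip count
and reported as infinite when the pure-birth boundary is the supremum),
density-dependent exponential (`DDX`, `lambda(N) = r N^-x`), and
piecewise-constant Yule models with one or two shifts placed on the observed
branching times with closed-form per-segment rates (`yule2rate` k = 3,
`yule3rate` k = 5 free parameters). ΔAIC_RC = AIC(best RC) − AIC(best RV);
negative values favour rate constancy, and the package reports alongside it
the decision thresholds 4.0 (about 30 tips) and 5.5 (about 100 tips) below
which rate constancy cannot be rejected with confidence. The likelihood
ratio between the two best models is referred to chi-square with 1 d.f.,
reproducing the reporting convention of the studies this battery mirrors
even though the parameter-count difference may be larger; the AIC ordering,
not this p-value, is the primary criterion.

`shift_at_time_test()` fits one rate before and one after a candidate shift
age (the straddling interval is split there; an event exactly at the shift
belongs to the younger segment) and compares against the constant fit with
chi-square d.f. 1. The bundled event ages — EOGM 34, LOWE 25, MMCO 15, PPG
2.6 Ma (`default_event_times()`) — are editable defaults for the named
paleoclimatic events, not fixed constants of the method. The relative
cladogenesis test evaluates, for each non-root internal node, the
probability under the equal-rates Markov null that a lineage present just
after its parent's split leaves at least the observed number of the tree's
tips (a uniform-compositions tail computed with log-binomials), Bonferroni
corrected over tested nodes. `ms_netdiv()` returns the Magallón–Sanderson
stem and crown estimators; at ε = 0 they reduce to `log(n)/t` and
`log(n/2)/t`.

## Synthetic data: what the generators emulate

The generators define the conditions every calibration and recovery test
runs under, with ground truth attached:

- `sim_yule()` / `sim_bd()`: constant-rate chronograms conditioned on the
  tip count. The birth–death simulator uses forward simulate-and-retry
  (retry cap 10,000), stopping when the extant count first reaches `n` and
  pruning extinct lineages; this simple stopping rule slightly biases the
  youngest internode interval relative to exact conditioned samplers, which
  is immaterial for its role here (recovery tests, not null calibration —
  the γ null always uses the exact Yule conditioning above).
- `sim_gmyc()`: a Yule species tree (optionally rescaled to `crown_age`,
  optionally redrawn until its youngest split is at least `min_split` — the
  "deep species tree" regime) whose tips are replaced by rescaled Kingman
  coalescent clusters with expected depth `theta`. The delimitation recovery
  tests use k = 5 species, 4 samples each, crown 1.0, `min_split` 0.1 and
  `theta` 0.005: a separation regime in which the true species are
  identifiable. Without the depth floor, a plain Yule species tree places a
  species split at the coalescent scale in a nontrivial fraction of
  replicates; those scenarios are genuinely unidentifiable from a
  single-locus tree and are flagged (`flag_unidentifiable`) rather than
  counted as delimitation failures. Within-species depths are i.i.d. across
  species; real barcode data add rate variation, varying effective
  population sizes, and non-random sampling that these tests do not probe.
- `perturb_rates()`: independent lognormal branch-rate noise with mean 1 and
  standard deviation `sigma`; it emulates uncorrelated rate variation only.
- `sim_dec_ranges()`: exact Gillespie simulation of the slice-stratified
  anagenetic process plus uniform scenario draws at nodes; whole-tree
  rejection of runs hitting the null range (count reported, abort after
  `max_reject`) makes tip ranges observable at the cost of conditioning on
  survival, the same conditioning the likelihood ignores — at the moderate
  rates used in the tests the induced bias is within the tested tolerances.
- `sim_seqs()`: Jukes–Cantor sequences via phangorn's simulator, sufficient
  to exercise consensus reduction and distance expectations.

Problem sizes in the test suite (100-tip trees, 50-replicate medians,
10,000-replicate Monte Carlo nulls, 500-replicate calibrations) were chosen
so each check pins its quantity within the asserted tolerance; they are
stated in the tests themselves.

## Known limitations

- MPL dating provides relative ages only and no rate-smoothing with
  multiple calibrations; the intended workflow passes a externally dated
  chronogram to the biogeographic and diversification stages.
- GMYC here is single-threshold and maximum-likelihood only (no multiple
  thresholds, no Bayesian variant); entity counts near the identifiability
  boundary carry wide confidence sets, which is why the 2-log-likelihood
  threshold set is always reported.
- DEC excludes founder-event (jump) speciation; extinction estimates from
  extant ranges are weakly informed; likelihoods with more than ~8 areas
  would need sparse methods not implemented here.
- The MCCR null assumes uniformly random taxon sampling; biased sampling
  (e.g. against rare, recently diverged species) shifts the critical value
  in ways the test cannot see.
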