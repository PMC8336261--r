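---
title: "Methods: family-level tests of venom-associated diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-level tests of venom-associated diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomdiv)
```

# Scope and data model

`venomdiv` asks whether a binary key innovation — venom — is associated with
elevated net diversification across families of a large radiation. The unit
of analysis is the *family*: the inputs are a rooted, time-calibrated,
family-level phylogeny (branch lengths in My, polytomies allowed) and a
per-family table of total species richness, a 0/1 venom state, and an
optional `mixed_state` flag marking families known to contain both venomous
and non-venomous species. Three statistically independent routes are
implemented and meant to be read together, because each rests on different
assumptions:

1. **Rate estimation and phylogenetic regression.** A closed-form
   method-of-moments estimator converts each family's richness and stem age
   into a net diversification rate; phylogenetic generalized least squares
   (PGLS) then models (a) log richness on rate, age, age², and venom, and
   (b) rate on venom, age, and age².
2. **Sister-clade contrast.** The richness Yule likelihood-ratio test
   compares total species richness between sister clades that differ
   uniformly in venom state.
3. **State-dependent diversification.** Constrained BiSSE-type likelihoods
   (and a hidden-state variant) treat the families themselves as tips and
   ask whether family-level branching rates depend on the trait.

A fourth component — Mk fitting plus stochastic character mapping —
estimates how often venom arose and what fraction of evolutionary history
was spent venomous.

# Tree conditioning

Family-level backbone trees often carry zero-length branches left by
polytomy handling. `condition_tree()` adds `pad` (default 0.5 My) to every
branch shorter than `pad` and then restores ultrametricity with a
non-negative least-squares adjustment (`force_ultrametric()`, delegating to
the standard nnls implementation; `method = "extend"` lengthens terminal
branches instead). Padding *all* branches is available via
`pad_all_branches = TRUE` but is not the default, because uniform padding
inflates every stem age used downstream. Note that the least-squares
correction can slightly shorten individual branches while equalizing tip
depths; the guarantees after conditioning are strict positivity and
ultrametricity (within 1e-8 My), not per-branch monotonicity.

Stem ages are read as the age of each tip's parent node — the time the
family split from its sister lineage — which exists for monotypic families
too (crown ages do not).

# Net diversification rates

For richness $n \ge 1$, stem age $t > 0$ and relative extinction
$\epsilon = \mu/\lambda \in [0, 1)$:

$$\hat r \;=\; \frac{1}{t}\,\ln\!\big(n(1 - \epsilon) + \epsilon\big),$$

the stem-age method-of-moments estimator. $\epsilon$ is a nuisance
parameter swept over $\{0, 0.5, 0.9\}$ by default, with reporting keyed on
$\epsilon = 0.5$. The estimator is exact in expectation for a pure-birth
clade and monotone in all three arguments; for short stems it is strongly
discrete (a monotypic family always gets $\hat r = 0$), which matters for
median summaries (see the generator section).

# Phylogenetic regression

`fit_pgls()` maximizes the multivariate-normal likelihood
$y \sim \mathcal N(X\beta,\; \sigma^2 V(\theta))$ where $V$ is built from
the tree under one of nine residual-covariance models: Brownian motion
(BM); Pagel's $\lambda$ (off-diagonal shrinkage, $\lambda \in [0,1]$);
$\kappa$ (branch lengths raised to $\kappa \in [0,3]$; $\kappa \to 0$ is
punctuational); $\delta$ (node depths raised to $\delta \in (0,3]$,
rescaled to tree height); early burst (rate $\propto e^{rt}$, $r \le 0$);
Ornstein–Uhlenbeck with a random (stationary) or fixed root
($\alpha \in (0, 50/T]$, reported with the phylogenetic half-life
$\ln 2/\alpha$); a trend model (BM plus a tip-height regressor — degenerate
on ultrametric trees, where it collapses to BM and is flagged); and
non-phylogenetic OLS (identity).

$\beta$ and $\sigma^2$ are profiled in closed form; the single covariance
parameter is optimized by a deterministic 25-point grid scan refined by
golden-section search, which is robust for these one-dimensional,
occasionally multimodal profiles and reproducible without random restarts.
Estimation is ML (not REML) so that AIC is comparable across
covariance models; `select_model()` fits all candidates and returns the
minimum-AIC fit, preferring the random-root OU under numerical ties and
then the model with fewer parameters. Standard errors come from
$\hat\sigma^2 (X^\top V^{-1} X)^{-1}$ with two-sided $t$ tests on $n - p$
degrees of freedom. Age enters the regressions raw (uncentred), so
coefficients are on the scale of My and My²; `center_age`-style rescaling
was deliberately not applied to keep coefficient scales interpretable
against family tables.

The lambda-model fit was validated against an independent GLS
implementation (`nlme::gls` with `ape::corPagel`): parameter, coefficients
and log-likelihood agree to at least six digits on simulated data.

# The richness Yule sister test

Under a pure-birth (Yule) process starting from one lineage, clade size
after time $t$ is geometric:
$\ln P(N = n \mid t, \lambda) = -\lambda t + (n-1)\ln(1 - e^{-\lambda t})$.
`find_sister_pairs()` extracts maximal uniformly-venomous clades and pairs
each with its sister when the sister is uniformly non-venomous (mixed
sisters are skipped and counted); both clades of a pair share the age of
their common parent node, since both daughters originate there. Total
species richness is summed over the families in each clade — the test
compares species, not tip counts. The likelihood-ratio statistic
$\chi^2 = 2(\ln L_1 - \ln L_0)$ contrasts separate venomous/non-venomous
rates against a shared rate on 1 degree of freedom. Rates are maximized on
the log scale (tolerance 1e-10). The implementation was checked to agree
with the independent implementation in `ape` to five digits.

With polytomies, the "sister" of a uniformly venomous child is the union of
all other children of its parent; if that union mixes states the candidate
pair is skipped. Because maximal uniform clades are disjoint, accepted
pairs never overlap, so no nested-pair tie-break is needed in practice.

# State-dependent diversification

The k-state speciation–extinction likelihood integrates, along each branch,

$$E_i' = \mu_i - (\lambda_i + \mu_i + \textstyle\sum_{j \ne i} q_{ij})E_i
        + \lambda_i E_i^2 + \textstyle\sum_{j \ne i} q_{ij}E_j,$$
$$D_i' = -(\lambda_i + \mu_i + \textstyle\sum_{j \ne i} q_{ij})D_i
        + 2\lambda_i E_i D_i + \textstyle\sum_{j \ne i} q_{ij}D_j,$$

with a compiled adaptive Cash–Karp Runge–Kutta scheme (rtol 1e-8, atol
1e-10 by default; fitting uses 1e-7/1e-9). At nodes,
$D_i \leftarrow D_i^{(1)} D_i^{(2)} \lambda_i$, multifurcations combined by
sequential pairwise products (order-invariant); $D$ is renormalized at
every node with log-compensation, so underflow cannot occur even on large
trees. At the root, states are weighted by their relative contribution to
the likelihood (FitzJohn weighting) and the likelihood is conditioned on
survival of both root lineages by default; both choices are exposed as
flags since analyses differ in convention. The implementation matches an
independent dense integrator (deSolve at rtol 1e-10) to better than 1e-6 on
reference trees, and satisfies the factorization identity (equal rates
$\Rightarrow$ birth–death $\times$ Markov-trait likelihood).

Five constrained binary-state variants are fitted: unconstrained (6 free
parameters), fully constrained (3), diversification-constrained (4),
speciation-constrained (5) and extinction-constrained (5), plus a
hidden-state variant with states (0A, 1A, 0B, 1B): $\lambda$ and $\mu$ free
per hidden state, observed-trait transitions shared across hidden classes,
and one shared hidden-switching rate $\eta$ (11 free parameters; no dual
transitions). The exact hidden structure is a documented package choice —
"a hidden state to allow rate variation" admits several parameterisations.
Optimization is L-BFGS-B on log parameters with a heuristic start (from
$\ln(\text{tips})/T$) plus jittered restarts under a fixed seed (8 by
default). Model choice is lowest AIC, except that within 2 AIC units the
model with fewer parameters wins — a more complex model must earn its
parameters.

**Caveat carried through from the design:** families are the tips, so
species richness does not enter the SSE likelihood at all; this route asks
about diversification of *family-level* lineages, and its parameter values
should be read cautiously (the adequacy check below quantifies absolute
fit).

`simulate_sse()` is an exact Gillespie simulation over lineages
(speciation, extinction, state change) to a fixed age with extinct lineages
pruned; `adequacy_check()` simulates (default 1000) trees under the fitted
model from the fitted root-state weights and locates the observed tip count
and venomous proportion within the simulated distributions.

# Trait history

`fit_mk_ard()` fits the 2-state all-rates-different Markov model by pruning
with closed-form 2×2 transition probabilities, root at the stationary
distribution (flag for equal priors; the choice matters little when
gain/loss rates are well separated). `stochastic_maps()` samples node
states from their joint conditional distribution and then samples each
branch's full history conditioned on its endpoints by uniformization —
exact, and robust on long branches with low rates, where rejection sampling
stalls. Summaries report the per-branch gain probability (the fraction of
maps with at least one gain on that branch), the distribution of gain and
loss counts (median, mode, range, central 95%), branches whose gain
probability exceeds a threshold (default 0.2), and the mean fraction of
total tree length spent venomous.

A property worth knowing when reading mapped counts: when loss is much
faster than gain, maps legitimately contain short-lived excursions that
leave no trace at the tips, so mapped transition counts sit above the
number of *observable* origins; the same behaviour is shown by the
reference implementation in `phytools`, with which our per-map counts agree
on shared data. Counts are therefore reported as distributions, and the
minimum across maps is the defensible "minimum number of origins".

# The synthetic-data generator

`gen_dataset()` composes three generators under one seed (R's default
Mersenne–Twister; fully deterministic given the seed):

* `gen_tree()` — pure-birth family tree with rate 0.01/My run to age
  $\ln(n)/\text{rate}$ (expected $n$ tips; ≈ 611 My for the default 450
  families). Because the Yule tip count is highly dispersed, draws outside
  [n/2, 2n] tips are redrawn and counted.
* `gen_traits()` — forward 2-state Markov simulation, gain 0.004/My and
  loss 0.03/My (stationary venom prevalence ≈ 11.8%, matching the ~10–16%
  prevalence regime of real family data), root drawn from the stationary
  distribution, full true history retained.
* `gen_richness()` — richness geometric with success $e^{-rt}$ given each
  family's stem age, i.e. the same Yule clade-size law the sister test
  uses, with $r_0 = 0.03$, $r_1 = 2 r_0 = 0.06$ per My — the "venomous
  families diversify about twice as fast" condition.

The tree rate was set to 0.01/My (not faster) so that median stem ages land
near 33 My, long enough for the rate estimator to be informative: with much
shorter stems most families are monotypic and per-family estimates collapse
to zero. Even so, the *median-of-estimates* ratio between venomous and
non-venomous groups overshoots the generative 2× (about 1.7–3.0 across
seeds), because the estimator's additive $-\mathcal O(1/t)$ small-clade
bias hits the slower group relatively harder. This is a property of the
summary statistic, not an error, and the tests encode the computed band.

What the generator deliberately does **not** emulate: real backbone
topologies (TimeTree-like family trees are far from Yule — real stem ages
are older and richness far larger at equal rates); richness overdispersion
beyond the Yule law; trait-dependent family-level branching (the default
tree is trait-independent, so state-dependent SSE variants should — and do
— lose to constrained ones on default synthetic data); and intrafamily
trait variation (the `mixed_state` flag must be set explicitly to exercise
the robustness rerun). Passing tests on synthetic data therefore validate
the estimators and their calibration, not the empirical claims themselves.

# Pipeline, reproducibility, and problem sizes

`run_all()` executes conditioning → rates → both regressions → sister test
→ SSE model set + adequacy → Mk + mapping, per $\epsilon$, with an optional
parallel rerun excluding `mixed_state` families, and writes TSV/JSON
reports. Every stochastic stage takes the config seed; a rerun with the
same seed reproduces every number exactly. Stage failures abort with the
stage name.

Problem sizes were chosen to keep a full laptop-scale run in minutes: the
test suite uses trees of 60–530 tips, 100–150 replicates for calibration
checks, 20 replicates for state-dependent recovery (~350–800 tips), 30
replicates of ~500-family datasets for gain/loss-rate recovery, and the
acceptance script runs the full pipeline on one default-scale dataset
(~450 families) with 1000 stochastic maps and 1000 adequacy simulations.

# Known limitations

* The PGLS trend model is undefined on ultrametric trees and silently
  reduces to BM there (flagged in the fit object).
* SSE fits on a few hundred family-level tips have limited power, and the
  hidden-state variant's 11 parameters are close to what such data can
  support; multi-start optimization mitigates but does not remove the risk
  of local optima.
* The sister test conditions on identified pairs; trees whose venomous
  families are scattered as singletons yield few pairs and a low-powered
  test (a warning is emitted below 2 pairs).
* Mapped origin counts are upper-bounded summaries of observable origins
  when loss rates are high (see above); the minimum across maps is the
  conservative figure.
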