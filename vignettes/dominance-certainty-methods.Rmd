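---
title: "Dominance certainty and status-health models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance certainty and status-health models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domcert)
```

# The problem

In group-living animals, dominance rank is the usual summary of social
status, but rank alone says nothing about how *settled* an animal's status
relationships are. Two animals can hold the same rank while one is
routinely deferred to and the other is continually contested. `domcert`
separates these two components: a linear **dominance rank** (expressed as
the proportion of groupmates outranked, 0 = bottom, 1 = top) and a
**dominance certainty** (DC) score in [0.5, 1] measuring how unambiguously
each animal fits the group-level flow of aggression. Both are then carried
into information-theoretic model selection over a fixed set of hypotheses
about health outcomes (pro-inflammatory biomarkers and diarrhea).

# Dominance inference

The input is a win/loss matrix of directed agonistic events (every
aggressive event is a win for the actor, whether or not a submission was
recorded — the network is built from all dyadic aggression). The inference
proceeds in five steps.

**1. Pathway enumeration.** All directed simple paths up to length
`max_path_len` (default 3) are counted between every ordered pair in the
binarized win digraph. A path A→B→C→D is indirect evidence that A
dominates D. Length-1 counts are the raw win counts, so direct evidence
scales with the number of observations; longer paths are counted as
distinct node-disjoint routes. For `max_path_len <= 3` the counts come
from closed-form adjacency-matrix algebra with non-simple walks
subtracted (exactness is tested against an exhaustive DFS oracle);
longer horizons use the DFS directly.

**2. Triad transitivity.** Each dyad is oriented by its majority win
direction; each fully oriented triad is transitive or cyclic, and
`t = transitive / (transitive + cyclic)`. Tied dyads leave the triad
uncounted rather than forcing an arbitrary orientation.

**3. Win imputation.** Indirect paths contribute imputed wins with weight

`g(t, l) = beta * max(2t - 1, 0)^(l - 1)`,   `l >= 2`, `beta = 0.5`.

The weight rises with transitivity (in a highly transitive network an
indirect path almost surely reflects true dominance), decays with path
length, vanishes when transitivity is uninformative (t <= 0.5), and is
always below 1, so a single direct win always outweighs any single
imputed win. This functional form is this package's design: it satisfies
all of those qualitative constraints, which is what the approach requires;
other forms satisfying them would be admissible.

**4. Dyadic dominance probability.** For each pair,
`DP_ij = P(X > 0.5)` with `X ~ Beta(w_ij + 1, w_ji + 1)` over the
weighted win counts. The add-one (uniform) prior makes a pair with no
direct or indirect evidence perfectly ambiguous (DP = 0.5), and
`DP_ij + DP_ji = 1` holds exactly. Dyadic certainty folds direction out:
`c_ij = max(DP_ij, 1 - DP_ij)`, and an animal's DC is its mean dyadic
certainty over all partners.

**5. Lowest-cost linear order.** The rank order minimizes
`cost(order) = sum of (1 - DP_ij)` over pairs placed i-above-j, so a
fully consistent probability matrix is cost-minimal at its true order.
Minimization is simulated annealing with adjacent-transposition proposals,
geometric cooling over `200 * N^2` proposals (T from 0.5 to 1e-4), a fixed
seed (default 0), and a final deterministic descent to the nearest
adjacent-swap local optimum. Zero-cost swaps are never accepted, so fully
ambiguous matrices return the input id order — a deterministic tie-break.
For networks of up to 7-8 animals the annealer provably attains the
exhaustive-permutation optimum in the test suite.

**Certainty categories.** For plotting and description, per-group DC
distributions are segmented into low / moderate / high by a continuous
two-breakpoint piecewise-linear regression of sorted DC on empirical
quantile (Muggeo-style iterative linearization, with an RSS grid search as
fallback and a Nelder-Mead polish of the knots). Groups are categorized
separately because their DC distributions differ.

**Sensitivity to non-independence.** Because network measures share edges,
`node_removal_sensitivity()` recomputes DC after deleting single animals
and reports Pearson and Spearman correlations with the original values.

# Health outcome models

The hypothesis set H0-H8 crosses sex, age category (juvenile 3, subadult
4-5, adult 6-12 = referent, geriatric 13+), rank, DC, and their
interactions up to sex x rank x DC. Controls enter every model: blood
sampling order for the biomarkers, IL-6 additionally for CRP, and a
log(observation days) offset for diarrhea bouts. Families are gamma (log
link) for CRP and negative binomial (NB2, log link) for IL-6, TNF-alpha
and diarrhea bouts, all with a random group intercept estimated by Laplace
approximation (via glmmTMB). Note that the interaction hypotheses (H6,
H7a, H7b) include a DC main effect, matching the fitted model formulas of
the reference selection tables rather than the terser hypothesis shorthand.

`AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with `k` counted as fixed
effects + 1 dispersion + 1 random-intercept variance. Model likelihoods
`L = exp(-dAICc/2)`, Akaike weights, and evidence ratios follow the
standard multimodel arithmetic; a candidate set is the single best model
when its weight is at least 0.90 and otherwise all models with
`dAICc <= 5`, excluding the null model (which carries no interpretable
status effect). Fits whose Hessian is not positive definite (typically a
variance component at its boundary) are flagged as non-converged and
dropped from selection with a warning.

Effect sizes are multiplicative: for a log-link coefficient `b` and a
predictor shift `delta`, the outcome changes by `exp(b * delta)`, reported
as an "x times increase/decrease". For predictors involved in
interactions, the effective slope adds each interaction coefficient times
the supplied moderator values.

# The synthetic colony generator

The generator exists so that every stage is testable without any animal
data; its defaults emulate a captive rhesus-macaque-like colony:

* **Hierarchy.** Latent scores equally spaced on [0, 1]; the
  higher-scored animal of a dyad wins with probability
  `plogis(steepness * score_difference)` (Bradley-Terry), steepness 130
  (log-odds across the whole hierarchy), so rank-adjacent contests are
  mildly decided (~0.75) and distant ones nearly deterministic.
* **Localized ambiguity.** Win probabilities are flattened toward 0.5 by
  `level * exp(-(d-1)/decay) * exp(-((m - 0.5)/width)^2)` where `d` is
  ordinal rank distance and `m` the dyad's rank midpoint (level 0.95,
  decay 20, width 0.15). Concentrating ambiguity among near-ranked,
  mid-hierarchy dyads reproduces the characteristic U-shaped DC-rank
  curve: animals at the top and bottom of the hierarchy have more certain
  relationships than those in the middle. A hard rank-adjacent band was
  tried first and rejected: against saturated 3-step pathway evidence it
  left no detectable U-shape, while the edge effect of distance-biased
  sampling (extreme-ranked animals have fewer near-ranked partners)
  dominated with the opposite sign.
* **Sparsity.** Dyads are sampled with weight `exp(-d/20)` and
  `0.80 * choose(N, 2)` events per group, which yields ~42-43% of dyads
  interacting and just under two interactions per interacting dyad —
  sparse enough that indirect pathways carry most of the information.
  Realized triad transitivity under these settings is 0.96-0.98.
* **Outcomes.** Log-linear predictors with rank, DC, rank x DC, sex, age,
  and sampling-order effects plus a group random intercept (SD 0.4);
  NB draws for cytokines, gamma for CRP, and a per-observation-day
  liquid-stool hazard `p = 1 - exp(-exp(eta))` on a twice-weekly 6-week
  calendar, aggregated by the same bout-counting rule the analysis uses.
  Daily hazards carry an animal-level lognormal frailty (SD 1.2):
  susceptibility to enteric upsets varies between individuals, and the
  aggregated bout counts are then genuinely overdispersed, keeping the
  NB dispersion identifiable. The diarrhea intercept (4.0) is set for a
  realistic colony prevalence (roughly half an expected bout per animal
  over the observation period).

**Effect sizes of the reference study** (`fixture_outcome_config()`).
The default coefficient sets are taken from a colony study's candidate
models. The reference synthetic study rescales the cytokine rank and
rank x DC terms so that the rank-slope reversal between low- and
high-certainty animals — the crossing pattern that motivates the
interaction hypotheses — occurs at the centre of the generator's own
realized DC range, with a log-slope span of about ±3 across it, and uses
NB size 16. This matters because inferred DC is a compressed, noisy proxy
of the generating DC (the saturated pathway evidence pushes dyadic
certainties toward 1): with coefficients calibrated to a real colony's
much wider DC range, the crossing point would fall entirely outside the
generator's range and no estimation procedure could recover the
interaction even in principle. The rescaled configuration keeps the
crossing structure while making it recoverable through the full
estimation pipeline.

**What passing tests do and do not show.** The generator produces a clean
linear hierarchy with stationary win probabilities, independent events,
and exactly the modeled outcome process. Real colonies have kin
structure, temporal rank dynamics, observer effects, and outcome
processes that are not log-linear in rank and certainty. Recovery results
on the fixture therefore validate the *machinery* (the inference recovers
what generated the data), not the biological model itself.

# Numerical choices and edge cases

* DP complementarity is exact by the Beta identity
  `P(X > 1/2; a, b) = P(X < 1/2; b, a)`; tests assert it to 1e-12.
* Pairs with no evidence sit exactly at DP 0.5; the diagonal is `NA`.
* Transitivity is `NA` (and imputation weights vanish) when no closed
  triads exist; networks with fewer than 3 animals skip the triad census.
* Annealing never accepts zero-delta swaps, making degenerate
  (all-ambiguous) inputs deterministic; equal-cost optima resolve to the
  input id order.
* The breakpoint fitter requires at least 10 animals and degrades
  gracefully: constant DC yields a single "moderate" category with a
  warning.
* Cytokine values below the 1.6 pg/mL detection threshold are set to 1
  (strictly below; 1.6 itself is kept). CRP above 10 is flagged but
  retained. Negative concentrations are fatal.
* Diarrhea bouts: a run of liquid-stool observation days continues across
  unobserved days and ends only at an observed clean day; empty records
  give (0 bouts, 0 observed days).

# Problem sizes used in the test suite

The suite exercises three groups of 114-126 animals (the reference
regime) for recovery checks — 20 seeded studies for rank recovery and the
interaction-sign check, three for transitivity and the U-shape — plus 50
negative-binomial simulations at n = 250 for coefficient coverage, and
exhaustive oracles at N <= 8 (paths), N <= 7 (permutations). These sizes
were chosen to hold Monte-Carlo noise well below the tested margins while
keeping a full run in the minutes range.

# Known limitations

* The imputation weight `g` and the Beta prior are reference
  formulations chosen to satisfy the approach's stated constraints; the
  exact weighting used by other implementations of
  percolation-and-conductance inference is not reproduced bit-for-bit.
* With 3-step pathways on ~120-animal groups the Beta evidence saturates,
  compressing inferred DC into roughly [0.93, 1.0]; DC is best read as a
  relative, within-group measure. Real colony analyses report wider DC
  ranges because their evidence per dyad is thinner relative to group
  size and their hierarchies less clean than the generator's.
* Dominance is treated as static over the observation window; there are
  no temporal dynamics, no kin structure, and no severity weighting of
  aggression (severity categories are parsed and retained but unweighted).
* Model selection assumes the candidate fits are comparable on the same
  data; animals with missing outcomes are dropped by the fitting routine,
  not imputed.
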