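---
title: "Methods: genetic search over population PK model structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic search over population PK model structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pkmoo` treats population pharmacokinetic (popPK) model development as a
combinatorial search: the modeler declares the hypotheses worth testing
(compartment count, covariate-effect forms, variability terms, residual
error models) and the package searches the cross-product of those
hypotheses with a single-objective hybrid genetic algorithm (SOHGA) and a
multi-objective NSGA-II.  This vignette records the model, the algorithmic
conventions, the numerical choices, and what the synthetic-data checks do
and do not demonstrate.

## Encoding: token sets and genomes

A *token set* is an ordered list of mutually exclusive options; each option
carries a structured payload for the decoder, a count of "effects" (units
of added complexity — one additional estimated parameter tied to a feature
counts as one effect, a "none" option counts zero), and the number of
θ/ω/σ parameters it adds.  A candidate model is a fixed-length bit string:
each token set occupies the smallest bit group with `2^b ≥ k` options, laid
out in declaration order.

Two conventions were genuinely open and are fixed as follows:

* **Plain binary decoding with modulo wrap.**  A bit group read as an
  unsigned integer `v` selects option `v mod k`.  This makes decoding total
  on all `2^n` genomes — crossover and mutation can never produce an
  invalid candidate — and keeps the reference decoder trivial.  Gray coding
  was rejected as it buys nothing once the modulo rule is in place.
* **Alias-uniform sampling.**  When a sampled option index is re-encoded,
  the bit pattern is drawn uniformly among the aliases `v ≡ index (mod k)`,
  so with uniform option weights the generator is uniform over genomes,
  not merely over options.

## The effect limit and its calibration

Clinical datasets rarely support more than a handful of covariate
relationships; unconstrained spaces waste evaluations on implausibly
complex candidates.  A configured *effect limit* is enforced in two
stages.  First, the raw generator weights option `o` within each token set
by `exp(-λ · n_effects(o))`, with `λ` chosen by bisection so that the
probability of a raw genome satisfying `total_effects ≤ limit` equals 80%.
That probability is computed exactly by dynamic-programming convolution of
the per-set effect distributions, so the calibration does not rely on
sampling.  Second, raw genomes exceeding the limit are discarded before any
model is evaluated and replaced by fresh draws; the 80% figure is therefore
a property of the raw generator only, and no evaluated model ever exceeds
the limit (the same filter is applied to downhill neighbours).

One subtlety: the sign of `λ` is *not* restricted.  On a space of six
binary 0/1-effect sets with limit 4, the uniform generator already yields
`P(total ≤ 4) = 57/64 ≈ 0.89`, above the target; reaching 80% requires
tilting *toward* effect-carrying options (`λ < 0`).  A non-negative tilt
could never achieve the stated calibration on such spaces.

## The evaluation engine

Candidate phenotypes are realized as linear compartment models:

* 1–3 disposition compartments, IV bolus or first-order oral absorption,
  optional absorption lag (`ALAG` shifts the depot input).
* Predictions by superposition of unit-dose responses.  One-compartment
  models use the closed forms (mono-exponential, Bateman); two- and
  three-compartment models use the eigendecomposition of the rate matrix,
  i.e. the matrix exponential.  The general engine is validated against
  hand-coded 1- and 2-compartment closed forms at `1e-8` relative
  tolerance.  If the eigenvector matrix is near-singular (reciprocal
  condition below `1e-12`, e.g. `KA` colliding with an elimination
  eigenvalue), `KA` is nudged by one part in `1e7` and the decomposition
  retried.
* Covariate effects scale structural parameters: `power`
  `(cov/ref)^θ`, `linear` `1 + θ(cov − ref)`, `exponential`
  `exp(θ(cov − ref))` for continuous covariates (centered at the dataset
  median of per-subject values), and `proportional_shift` `1 + θ·cov` for
  discrete 0/1 covariates (reference 0).
* BSV is log-normal per flagged parameter; BOV adds an occasion-indexed
  log-normal deviate with one shared ω per parameter, occasions read from
  an `OCC` column.  Within an occasion the subject's parameters are
  constant and all prior doses contribute under the current occasion's
  parameters — a deliberate approximation that avoids integrating a
  piecewise-constant system.
* Ω is diagonal throughout; correlated random effects are out of scope.

### Likelihood

The marginal likelihood uses the first-order conditional approximation
with interaction.  For subject `i` with empirical-Bayes mode `η̂ᵢ` (found
by damped Gauss–Newton on the penalized linearized objective, tolerance
`1e-7`, at most 20 iterations, restarted from zero on numerical failure):

```
-2 ll_i = log|V_i| + r_i' V_i^{-1} r_i,
V_i = G Ω G' + R(f(η̂_i)),   r_i = y_i − f(η̂_i) + G η̂_i,
```

with `G` the finite-difference Jacobian of the prediction in `η` and `R`
the residual variance evaluated at the *individual* prediction (the
interaction).  The additive `n log 2π` constant is omitted — the
convention of the standard estimation software in this field — because
only OFV differences drive the search.  Singular `V_i` or non-finite
arithmetic yields an infinite contribution, reported as non-convergence,
never an error.  The empirical-Bayes modes are re-solved from zero at
every objective evaluation so that the objective is a pure function of the
parameters; warm-starting them across evaluations makes finite-difference
gradients inconsistent and reliably stalls the optimizer.

### Estimation and diagnostics

`fit()` minimizes the OFV over `(θ, ω, σ)` with positive-constrained
components log-transformed, using `nlminb`.  On apparent non-convergence
up to two restarts are taken from jittered starting values; the jitter
comes from a small linear congruential generator keyed by the fit seed, so
evaluation never touches R's global RNG stream and results are independent
of evaluation order and worker count.  The covariance step is a central
finite-difference Hessian (relative step `1e-4`); it is accepted when all
eigenvalues exceed `1e-10`.  From it come the estimate correlation matrix,
the condition number — defined here as the eigenvalue ratio of the
*correlation* matrix, a convention choice the source conventions leave
open — and relative standard errors.  The high-correlation flag is strict
(`|r| > 0.95` fails; exactly 0.95 passes), and the condition-number flag
fires above 1000.  When the covariance step itself fails, the correlation
and condition checks are recorded as not-failed: the covariance penalty
already accounts for the failure and double-charging would distort the
fitness.

## Composite fitness (single-objective path)

`fitness = OFV + 10·#θ + 10·#ω + 10·#σ + 100` for each failed diagnostic
(convergence, covariance, correlation, condition number), all constants
overridable.  The multi-objective path never sees these penalties: its
objective vector is exactly `(OFV, NEP)` with `NEP = #θ + #ω + #σ`, and
diagnostics are carried along purely for reporting.

## SOHGA conventions

The published hyperparameters (population 80, 20 generations, crossover
0.95, mutation 0.95, 4 elites, 2 niches of radius 2, downhill every 5
generations) are the defaults.  Where the mechanism itself was
unspecified, the package fixes:

* **Single-point crossover** — the simplest standard operator consistent
  with a bare "crossover rate".
* **Per-candidate one-bit mutation** — the printed rate (0.95) is read as
  the probability that a candidate mutates at all, flipping one uniformly
  chosen bit; a per-bit rate of 0.95 would randomize the genome.
* **Tournament of distinct pairs** — two distinct members are drawn per
  tournament (with replacement across tournaments); the lower fitness
  wins; ties break by lower NEP then lexicographic bit string.  That
  triple (fitness, NEP, bit string) is the total order used for every
  tie-break in the package, making all trajectories deterministic under a
  seed.
* **Niching** — records are scanned by ascending fitness; a record founds
  a niche if its Hamming distance to every existing head exceeds the niche
  radius, until the configured number of heads exists.  Elitist slots are
  filled round-robin across niche heads, then by global fitness.  Downhill
  chains are seeded from the niche heads, and their results replace the
  worst population members.
* **Downhill** — steepest descent: all one-bit neighbours are evaluated
  and the single best strictly improving move is taken; on stall, one
  two-bit sweep is made and, if it improves, the one-bit loop resumes.
  The returned model is a one-bit (and, when enabled, two-bit) local
  minimum, never worse than the seed.

## NSGA-II conventions

The canonical generational scheme is used: crowded binary tournament
(front rank, then crowding distance), crossover and mutation as above,
effect-limit discard-and-replace of offspring, then environmental
selection over parents ∪ offspring (fill by rank; truncate the partial
front by descending crowding distance).  Boundary members of a front get
infinite crowding distance; a front of one or two members is all-boundary;
an objective constant across a front contributes nothing.  Before
truncation the front is put in a canonical (OFV, NEP, bit string) order so
that the boundary assignment — and therefore selection — does not depend
on pool order.

Three configuration keys need comment.  `elitist_num` is accepted but
ignored on this path (with a logged notice): environmental selection over
the combined parent–offspring pool already preserves every rank-1 member
that fits, which is the canonical algorithm's elitism.  `num_niches` and
`niche_radius` are parsed but play no role in the multi-objective path;
they are documented as unused rather than given an invented meaning.

The multi-objective downhill evaluates the bit-flip neighbourhoods of
every archive member and merges any candidate not dominated by the current
archive, pruning newly dominated members; a stalled one-bit pass triggers
a two-bit pass; the loop ends when neither adds a member.  This acceptance
rule — the weakest that can only improve the front — is a design choice,
since the source conventions state only that the local search is driven by
OFV and NEP.  The reported archive is the rank-1 front over *all*
evaluated models (not only the final generation), with duplicate
`(OFV, NEP)` pairs deduplicated keeping the lexicographically smallest bit
string; the final generation's front is reported alongside.

## Synthetic data: what it emulates, what it does not

`generate_dataset()` simulates rich designs (every subject observed at
≥ 15 nominal post-dose times) and sparse designs (1–3 uniform times per
subject within the last dosing interval, the therapeutic-drug-monitoring
shape typical of antipsychotic concentration datasets).  Covariates are
drawn from declared distributions; BSV/BOV and residual error follow the
true model; additive-error datasets may contain negative observations,
which are retained (no truncation or BLQ mechanism exists in the
generator).  Default cohort sizes are desk scale (≤ 100 subjects), chosen
so the full search and diagnostic loop runs in minutes on one core.

Real concentration data differ in ways the generator deliberately omits:
assay quantification limits and censoring, dose-history errors, dropout,
covariate correlation and measurement error, model misspecification, and
nonlinear (saturable) kinetics.  Passing the package's checks therefore
demonstrates that the algorithms and the estimator are internally correct
and mutually consistent — not that any particular real dataset is well
served by a given search space.

The enumerable 10-bit benchmark used for search-recovery checks assigns
each option a fixed OFV contribution plus mild pairwise interactions
between a few token-set pairs.  That surface mimics how model features
behave in practice — approximately additive OFV changes with some
epistasis (a variability term mattering only alongside the matching
structural feature) — while remaining exactly enumerable so the true
Pareto front and global optimum are known.  On an i.i.d.-noise surface
with no feature structure, no genetic search could be expected to recover
the exact per-NEP optima; that regime is outside what model selection
looks like.

## pcVPC choices

The prediction-corrected VPC bins observations into (by default 8)
quantile-based time bins — equal observation counts stabilize percentiles
on sparse designs — and corrects each observed and simulated value by
`bin-median PRED / PRED`, with `PRED` the population prediction (η = 0,
covariates included).  Rows with `PRED = 0` are excluded with a logged
count.  Percentiles use the linear-interpolation estimator (`quantile`
type 7) everywhere so tables are bit-reproducible under a fixed seed.  The
default of 1000 replicates matches standard practice; the across-replicate
90% interval of each percentile is reported.  Lower-bound correction for
below-quantification data is not implemented, consistent with the
generator producing none.

## Problem sizes used by the checks

The package's own test battery runs at desk scale, chosen as the smallest
sizes at which each property is sharply testable: 20,000 raw draws for the
sampler calibration (binomial 99% CI half-width ≈ 0.7 percentage points);
200-model populations for sorting-oracle equivalence; a 10-bit (1024
model) benchmark with 20 seeded runs for exhaustive-recovery checks; 20
replicates of a 50-subject, 15-sample rich design for parameter recovery
(median absolute relative error of CL, V, KA within 15%); and 20 pcVPC
self-consistency runs of 30 subjects × 1000 replicates with nominal 90%
coverage of the observed median.

## Known limitations

* FOCE-I here is a lightweight re-implementation: no ODE models, no Ω
  blocks, no SAEM/importance sampling, and finite-difference Jacobians
  throughout.  OFV values are comparable *within* this engine but not
  numerically interchangeable with other estimation software.
* The BOV prediction approximation above biases multi-dose BOV fits when
  occasions are short relative to the drug's memory.
* Condition numbers on the correlation matrix are bounded below by 1 but
  are not the same diagnostic as covariance-matrix conditioning; the
  threshold of 1000 should be read against this definition.
* `num_parallel` is honored as a contract (results are worker-count
  independent because evaluation is deterministic and order-free), but
  evaluation currently runs on one core.
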