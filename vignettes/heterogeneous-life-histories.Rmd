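---
title: "Stochasticity and heterogeneity in stage-classified life histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochasticity and heterogeneity in stage-classified life histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifemix)
library(dplyr)
```

## The model

`lifemix` analyses a breeding-state life cycle on an annual projection
interval. Four transient stages are indexed in a fixed canonical order —
pre-breeder (`PB`, has never bred, including fledged chicks), successful
breeder (`S`), failed breeder (`F`), non-breeder (`NB`, has bred before but
skipped this season) — plus death as an absorbing state. Three vital rates
parameterize every transition, each stage-specific and each a probability:

* `sigma_j` — annual survival of stage `j`;
* `beta_j` — probability of breeding next season, *given* survival;
* `gamma_j` — probability of raising the chick to fledging, *given*
  survival and breeding.

Within a year the events are ordered survive → breed → succeed, matching the
conditional definitions of `beta` and `gamma`. The resulting transient
matrix (columns = from-stage; the package works with column-stochastic
matrices and column population vectors throughout) is

$$
U = \begin{pmatrix}
(1-\beta_1)\sigma_1 & 0 & 0 & 0\\
\sigma_1\beta_1\gamma_1 & \sigma_2\beta_2\gamma_2 & \sigma_3\beta_3\gamma_3 & \sigma_4\beta_4\gamma_4\\
\sigma_1\beta_1(1-\gamma_1) & \sigma_2\beta_2(1-\gamma_2) & \sigma_3\beta_3(1-\gamma_3) & \sigma_4\beta_4(1-\gamma_4)\\
0 & \sigma_2(1-\beta_2) & \sigma_3(1-\beta_3) & \sigma_4(1-\beta_4)
\end{pmatrix},
$$

with mortality row `M = 1 - colSums(U)` completing the column-stochastic
chain. Two structural zeros encode the biology: the pre-breeder stage is
never re-entered, and a surviving pre-breeder that does not breed stays a
pre-breeder rather than becoming a "non-breeder" (that stage is reserved for
experienced birds).

Unobserved heterogeneity is modelled as a *finite mixture*: `g` latent
groups, each with its own full set of 12 vital rates, and a mixing
distribution `pi` giving the probability that a fledgling belongs to each
group. Membership is fixed for life. The packaged fixture
`southern_fulmar()` carries the published model-averaged rates for the
southern fulmar with `g = 3` and `pi = (0.14, 0.67, 0.19)`.

```{r}
fulmar <- southern_fulmar()
fulmar
```

## Demographic outcomes per group

All outcome machinery rests on the fundamental matrix
`N = (I - U)^{-1}` (a conditioned linear solve, never an explicit inverse;
the solve refuses to proceed when the reciprocal condition number of
`I - U` falls below 1e-12, which happens exactly when no absorbing state is
practically reachable, e.g. `sigma = 1` everywhere). `N[i, j]` is the
expected number of annual censuses spent in stage `i` before death, starting
from stage `j`.

**Time convention.** Occupancy counts include the starting census, so
diagonal entries of `N` are at least 1 and "life expectancy at fledging" is
the full column sum `1'N` for a `PB` start. Ages are annual step counts
since fledging. This convention makes the analytic moments directly
comparable with the individual-based simulator, which likewise counts the
fledging census as year 0 of a life.

Occupancy variances use `V = (2 N_dg - I) N - N ∘ N`; longevity moments use
`1'N` and `1'N(2N - I) - (1'N) ∘ (1'N)`; lifetime reproductive output (LRO)
is the occupancy of `S` — one chick per successful season — so its mean and
variance are row `S` of `N` and `V`.

```{r}
round(fundamental_matrix(fulmar$chains[["UH-3"]]), 2)
longevity(fulmar$chains[["UH-3"]])
```

### Conditional first-passage times

The age at first reproduction, age at first successful reproduction and
inter-breeding intervals are first-passage times to *entry* into a target
stage set. `first_passage()` redirects every transition into the target to a
new absorbing "event" state competing with death, computes the event
probability `b(j)` from each stage, and conditions on the event by the
standard Bayes reweighting of the transient matrix,

$$U^c(i,j) = U'(i,j)\,\frac{b(i)}{b(j)},$$

dropping stages with `b = 0` (they are reported with a `no_path` flag and
`NA` moments, never `NaN`). The conditional chain's fundamental matrix then
yields the conditional mean and variance of the passage time. Because only
*incoming* transitions are redirected, a chain may start inside the target:
an inter-breeding interval starts at a breeding stage and waits for the next
entry.

Two conventions deserve flagging:

* **Recruitment versus first success.** "First reproduction" targets
  `{S, F}` (an attempt of either outcome); "first successful reproduction"
  targets `{S}` with failed attempts en route treated as transient detours.
  The two differ for groups whose `gamma_PB < 1`.
* **Inter-breeding interval.** `breeding_interval()` defaults to the time
  until the next *successful* season (target `{S}`). That is the convention
  under which the published fulmar interval table reproduces entry for
  entry; the natural alternative — time to the next attempt, target
  `{S, F}` — is exposed as `type = "attempt"` and gives systematically
  shorter intervals.

```{r}
outcome_table(fulmar) |> filter(outcome == "breeding_interval")
```

### Adult-life occupancy

Whole-life occupancy proportions start at `PB`. For "adult life" summaries a
starting distribution is needed and the natural one is the outcome of the
recruitment event itself: weight `gamma_PB` on `S` and `1 - gamma_PB` on `F`
(`recruitment_start()`). This is an interpretive choice — starting all
recruits in `S` gives proportions within a couple of points here — but the
recruitment-weighted start is the one consistent with the life-cycle event
ordering, and it is the package default.

## Heterogeneous cohorts

A mixed fledgling cohort is a stage-by-group vector (group-major ordering:
stages contiguous within each group). It is projected by the block matrix
`Ũ = Kᵀ D K U`, where `U` is block-diagonal in the per-group transient
matrices, `D` is block-diagonal in per-stage `g x g` group-transition
matrices, and `K = vec_permutation(s, g)` converts group-major to
stage-major ordering. With fixed heterogeneity every `D_i = I` and `Ũ`
collapses exactly to the group blocks — an identity the test suite asserts —
but the interface accepts arbitrary column-stochastic `D_i`, so dynamic
heterogeneity is expressible. The explicit index map in
`?vec_permutation` exists to prevent silent transposition bugs, which are
the classic failure mode of block-structured projections.

Projection is pure attrition (no recruitment feedback): the default horizon
is 100 years and the default initial cohort puts `pi` on the pre-breeder
stages. `cohort_composition()` reports survivorship and the group/stage
shares among survivors, with shares flagged `NA` (not `NaN`) once the cohort
is numerically extinct.

```{r}
traj <- project_cohort(fulmar, horizon = 100)
cohort_composition(traj) |> filter(t == 100, unit == "group")
```

The fixture shows the classic two-phase selection: the frail-juvenile
majority group UH-2 first shrinks among survivors (its pre-breeders die
young), then — because its *adults* survive best — recovers and approaches
fixation, while total survivorship at age 100 is of order 0.1%.

## Variance decomposition

For any outcome `xi`, the law of total variance over the mixture splits the
inter-individual variance exactly:

$$V(\xi) = \underbrace{E_\pi V(\xi_k)}_{\text{within: individual stochasticity}}
 + \underbrace{V_\pi E(\xi_k)}_{\text{between: heterogeneity}}.$$

`decompose_variance()` is the bare arithmetic (the identity
`total = within + between` holds exactly by construction);
`decompose_outcome()` wires the per-group analytic moments into it.

For age at first reproduction, the group moments are conditional on
recruiting before death, and the default weights are the *unconditional*
mixing distribution: a group enters with its fledgling share even if only
10% of its members ever recruit. This choice reproduces the published
between-group component from the published conditional means; the
alternative — re-normalizing `pi` by each group's recruitment probability —
is available via `weights = "conditional"` but is not the default, because
it answers a different question (variance among eventual recruiters).

```{r}
variance_table(fulmar)
```

## The simulator as independent oracle

`simulate_cohort()` realizes the same mixture process event by event:
group membership i.i.d. from `pi`, then per year survive → breed → succeed
with the current stage's rates. It shares *no* code with the matrix
analytics — no fundamental matrix, no conditioning — so agreement between
the two is a genuine cross-check, and the test suite requires the simulated
means and variances of longevity, LRO and first-passage outcomes to sit
within three standard errors of the analytic values at `n = 1e5` for every
group, and pooled variances to satisfy the law of total variance.

Implementation choices worth knowing:

* The cohort engine is vectorized year-by-year over all living individuals
  with a single seeded RNG stream; a given `(seed, n)` pair reproduces the
  outcome table byte for byte. (Per-individual substreams would let `n`
  grow without reshuffling earlier individuals, but would force an
  interpreted per-individual loop for no inferential gain.)
* Lifespans are capped at 1,000 years as a safety net; survivors at the cap
  are flagged `censored`, never silently truncated. With the fixture rates
  the probability of reaching the cap is negligible (adult survival ≤ 0.99
  gives P(alive at 1,000) < 1e-4 even before breeding mortality).
* `simulate_captures()` overlays stage-dependent (optionally
  group-dependent) detection on the latent trajectories to emulate a
  multistate mark–recapture data set; the banding occasion is always
  observed. No detection probabilities are published for the fixture, so
  they are a required user argument. Fitting mixture mark–recapture models
  to these tables is deliberately out of scope — the export exists so that
  such estimation can be tested elsewhere.

What the simulator does *not* emulate about real field data: temporal
variation in rates (sea-ice effects), permanent emigration distinguishable
from death, band loss, or age effects within the pre-breeder stage. Passing
oracle tests therefore validate the *mathematics* of the chain analysis,
not the adequacy of a fixed-rate four-stage model for any particular data
set.

## Numerical choices and problem sizes

* Linear solves are guarded by a reciprocal-condition-number threshold of
  1e-12, and errors name the offending group.
* Event probabilities are clamped to `[0, 1]` against roundoff at the
  boundary (chains with `sigma_PB = 1` produce `b = 1 + 2e-16` otherwise).
* Tiny negative occupancy variances from floating-point cancellation
  (> -1e-9) are set to zero; anything more negative would indicate a bug
  and is left to fail the non-negativity invariant.
* Published golden values are asserted at tolerances implied by the inputs
  being printed to two decimals: 0.05 absolute on fundamental-matrix
  entries, 0.1 on first-passage means (0.01 on probabilities), 2% relative
  on variance components.
* The test suite simulates 2e4-sized cohorts for smoke checks and one
  1e5-sized cohort for the oracle-equivalence block (~0.4 s); projections
  run to 300 years to check asymptotic fixation. These sizes keep the whole
  suite under ten seconds while leaving Monte Carlo standard errors small
  enough for three-standard-error assertions to bite.

## Limitations

Heterogeneity is fixed at fledging: the machinery for dynamic group
transitions exists in the projection (`D` blocks) but outcome analytics and
the simulator assume fixed membership. The stage space is hard-wired to the
four breeding states, which is what the shipped parameterization is about;
generalizing the stage set would touch only the constructors, but is not
attempted. No estimation from capture–recapture data is provided, and no
sensitivity or selection-gradient analysis of the outcomes.
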