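---
title: "Methods: simulating and phenotyping the probabilistic-delivery task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and phenotyping the probabilistic-delivery task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtask)
```

## The task and its geometry

In the probabilistic-delivery task (PDT) a subject repeatedly chooses between
two operanda: a "Small & Sure" (SS) hole that always delivers 1--2 food
pellets, and a "Large & Luck-Linked" (LLL) hole that delivers 5--6 pellets
with a session-wide probability $p$ imposed by the experimenter. Across the
testing phase $p$ is rarefied over seven levels (100%, 50%, 33%, 25%, 20%,
17%, 14%). Two species presets encode the standard parameterizations: rats
run one 25-minute session per level with a 15-second post-choice timeout, and
marmosets run three consecutive 5-minute sessions per level with a 6-second
timeout (21 testing sessions in all).

Two analytic quantities follow directly from the geometry. The **odds** of a
delivery probability are the mean number of omissions before a success,
$\mathrm{odds} = 1/p - 1$, with inverse $p = 1/(\mathrm{odds}+1)$. The
**indifferent point** of a large/small reward ratio $r$ is the probability at
which expected payoffs coincide, $p^\ast = 1/r$: 20% for a 5-fold ratio and
33% for a 3-fold ratio, so the nominal 3- to 5-fold reward range spans an
indifference zone of $p \in (0.20, 0.33)$. Below the zone the large reward is
the economically dominant choice; beyond it, repeatedly choosing SS maximizes
intake. The pellet ranges themselves admit realized ratios of 2.5--6; the
reward specification therefore carries *declared nominal* ratios (3, 5) for
zone arithmetic, with the realized-pellet alternative available via
`indifference_zone(..., nominal = FALSE)`. Probabilities are stored as
fractions in $(0, 1]$ throughout the internals and printed as percentages at
the interfaces, and the set levels 33% and 17% are taken as the exact
two-digit session parameters 0.33 and 0.17, not as $1/3$ and $1/6$: they are
experimenter-chosen dials, not derived quantities.

## Dependent variables

For each subject-session the package reduces the trial log to:

* `pref_LLL` — percent LLL choices over all completed trials, the gambling-
  proneness measure;
* `trials_per_min`, `pellets_per_min` — throughput over the *nominal* session
  duration (sessions have fixed length, so the nominal duration, not the time
  of the last trial, is the denominator);
* `persistence` / `restlessness` — mean inadequate (timeout-window) pokes per
  completed trial toward the LLL and SS hole respectively, indexing
  perseveration and uncertainty-driven motor impulsivity. The denominator is
  *all* completed trials of the session, not only omission trials, and pokes
  during rewarded-trial timeouts are counted: the per-session "per trial"
  average is taken at face value, and the attribution of timeout pokes to
  omissions is left to the generative model rather than the metric;
* `experienced_p` — the realized delivery percentage on the subject's own LLL
  choices, $100 \cdot \mathrm{successful\ LLL}/\mathrm{total\ LLL}$, and
  `experienced_odds` $= 100/\mathrm{experienced}_p - 1$. Because delivery is
  Bernoulli per trial, the experienced odds fluctuate around the set odds and
  are the subject-specific x-axis against which preference is normalized.

Sessions in which the subject never chose LLL, or chose LLL but was never
rewarded (experienced $p = 0$), have no finite experienced odds. These yield
missing values with a warning and are excluded from the preference-odds fit;
no continuity correction is applied, since inventing a capped odds value
would distort the x-axis for exactly the subjects whose LLL sampling is
thinnest. Zero-trial sessions are legal and propagate as missing per-trial
metrics with zero rates.

## Phenotyping procedure

1. **Inclusion.** A subject enters the analysis only if its mean `pref_LLL`
   over the sessions at the inclusion levels ($p$ = 100% and 50%, the levels
   before the indifference zone) is *strictly* greater than 60%. The
   inequality is strict (a subject at exactly 60.0% is excluded), and for
   marmosets the mean runs over all three replicate sessions at each level —
   the protocol leaves open which replicates to use, and averaging uses all
   of the information.
2. **Slope.** For each included subject, ordinary least squares of per-session
   `pref_LLL` on $\log_{10}(\mathrm{experienced\ odds} + 1)$ over all usable
   testing-phase sessions (rats contribute up to 7 points, marmosets up to
   21; $p$ = 100% sessions sit at $x = 0$). Base 10 follows the spreadsheet
   convention of the field; the choice is immaterial to the classification,
   since changing the base rescales every slope by the same positive factor —
   a property the test suite asserts. Sessions with index below the
   protocol's `first_test_session` are treated as training and ignored.
3. **Median split.** Within each species, included subjects are split on the
   median of their signed slopes: strictly below (steeper decline) →
   `non_gambler`, strictly above → `gambler`. A subject sitting exactly at
   the median (odd cohorts) is assigned to the provisional group its slope is
   closest to. "Closest" needs a metric the procedure's verbal description
   does not supply; the default is distance to the provisional group's mean
   slope (the least arbitrary summary), with distance to the nearest member
   available as `tie_rule = "nearest-neighbor"`, and exact equidistance
   resolving to `non_gambler`. The split is computed on included subjects
   only, independently within species by default (`pool_species = TRUE`
   offers the pooled reading). Cohorts in which all slopes are equal have no
   separable subpopulations and raise an error rather than an arbitrary
   split.

## The synthetic-cohort generator

No trial-level animal data accompany the protocol, so the generator exists to
give every downstream stage a testable input with the statistical structure
the analysis assumes. A synthetic subject is described by:

| parameter | units | default (demo) | role |
|---|---|---|---|
| `intercept_a` | % | 100 | baseline %LLL at odds 0 |
| `slope_b` | % per $\log_{10}(\mathrm{odds}+1)$ | −10 (flat) / −90 (steep) | preference decline |
| `rate_lambda` | trials/min | 2.4 (rat), 12 (marmoset) | free-operant response rate |
| `rate_compensation_c` | — | 0 (flat) / 0.5 (steep) | throughput inflation with rarefaction |
| `persistence_rho` | pokes/omission trial | 2 (flat) / 0.5 (steep) | LLL-hole timeout pokes |
| `restlessness_rho` | pokes/omission trial | 0.5 (flat) / 2 (steep) | SS-hole timeout pokes |
| `background_rho` | pokes/rewarded trial | 0.2 | timeout pokes on rewarded trials |

Within a session at set probability $p$: the trial count is Poisson with mean
$\lambda (1 + c \log_{10}(\mathrm{odds}+1)) T$, emulating free-operant
responding with individually variable rates (zero-trial sessions are legal);
each trial chooses LLL with probability
$\mathrm{clamp}(a + b\log_{10}(\mathrm{odds}+1),\,0,\,100)/100$; LLL delivery
is Bernoulli($p$) independently per trial; pellets are uniform on the
configured range when delivered and zero on omissions; and inadequate-poke
counts are Poisson at the omission rates on omission trials and at the
background rate otherwise, with no within-timeout temporal structure (only
counts per trial are analyzed).

Two modelling commitments deserve emphasis. First, the generative preference
is **linear in log-odds**, the same family the analysis fits, which makes
slope recovery well-posed: the recovery tests probe estimation error, not
model mismatch. A logistic or reinforcement-learning generator would be more
mechanistic but would conflate the two. Second, generation uses **set** odds
while the analysis uses **experienced** odds — mirroring reality, where the
animal faces the programmed schedule but the analyst observes realized
deliveries. The gap between the two axes shrinks as trial counts grow and is
itself a tested property (at $p = 0.20$ with $10^4$ LLL trials, experienced
odds fall within $4 \pm 0.5$ in at least 99 of 100 seeded runs).

Demo trial rates give roughly 60 completed trials per session. No per-session
trial counts are published for either species, so the default is chosen for
statistical power — enough trials that a 7-point (rat) fit recovers
well-separated slopes — rather than fidelity to any particular animal.

What the generator does *not* emulate: within-session learning or satiation,
choice autocorrelation, latencies and intertrial timing, near-miss or
secondary-reinforcement effects, and session-to-session carryover. Passing
recovery tests therefore demonstrates that the pipeline correctly inverts its
own generative assumptions at realistic trial counts, not that real animals
satisfy those assumptions.

## Reproducibility and numerical choices

Cohort simulation derives one RNG substream per (agent, session) from the
master seed by drawing a seed matrix under the master seed, so logs are
byte-identical across reruns and invariant to evaluation order; the caller's
RNG state is preserved. The slope fit is ordinary least squares via `lm()`;
the test suite checks it against an independent normal-equations oracle to
1e-9 on a thousand random inputs. Degenerate inputs are handled explicitly:
fewer than two usable fit points, constant experienced odds, all-equal
slopes, and empty sessions each produce a named error or a flagged missing
value rather than a silent number. `run_pipeline()` writes a manifest (seed,
configuration hash, package and R versions, artifact hashes) that is
identical across reruns of the same configuration; stage timings go to
messages, not the manifest, precisely so the manifest stays reproducible.

Verification problem sizes: parameter recovery runs 100 seeded replicates of
a 12-subject rat cohort (6 flat $b=-10$, 6 steep $b=-90$, $a=100$, ~60
trials/session), requiring at least 95% correct labels and mean absolute
slope error at most 15 %/log-unit; odds convergence uses 100 sessions of
$10^4$ trials; the qualitative throughput/poke-profile check uses one
12-subject marmoset cohort. These sizes were chosen so that each statistical
assertion has comfortable power at its stated tolerance.

## Worked example

```{r example, eval = FALSE}
protocol <- default_protocol("rat")
agents   <- demo_cohort("rat", n_per_group = 6)
log      <- simulate_cohort(agents, protocol, seed = 1)
metrics  <- cohort_metrics(log, protocol)
profiles <- classify_cohort(metrics, protocol)
summary  <- group_summary(metrics, profiles)
plot_preference_odds(metrics, profiles)
```

or, equivalently, `run_pipeline(list(protocol = "rat",
simulate = list(agents = "demo", seed = 1)), out_dir = "run1")`, which also
writes the event log, metric, profile and summary tables as CSV plus the run
manifest.

## Known limitations

* The classifier is the median-split procedure by construction: it always
  labels half of each included cohort gamblers, so it measures *relative*
  proneness within a cohort, not an absolute phenotype; continuous scores or
  model-based clustering are deliberately out of scope.
* Slope estimates from 7-point rat fits are noisy for subjects whose LLL
  sampling collapses at low $p$ (few LLL trials → volatile experienced odds,
  occasionally no usable odds at all); the marmoset schedule's 21 points are
  materially more stable.
* Group summaries report means and SEMs per species × strategy × level
  (replicate sessions averaged within subject first); inferential statistics
  on those tables (repeated-measures ANOVA, post hocs) are intentionally left
  to dedicated statistical software.
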