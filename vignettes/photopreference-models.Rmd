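---
title: "Spontaneity, individuality, and the analysis of fly photopreference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spontaneity, individuality, and the analysis of fly photopreference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flychoice)
```

## The scientific question

When a group of *Drosophila* is offered a choice between a bright and a
dark arm, roughly 70% walk to the light. Two very different generative
accounts produce that same group-level number:

* **Spontaneity** — every fly shares the same choice probability
  $p$, and successive choices are independent coin flips. Select the flies
  that chose dark and test them again: they redistribute exactly like the
  original group. This is the classic observation on phototactic
  sorting — re-tested subgroups show "the same percentage" again.
* **Individuality** — each fly carries a stable latent preference
  $p_i$ drawn from some distribution across the population. A single
  choice barely reveals $p_i$, but over many choices the flies sort
  themselves: animals with an extreme run of first choices keep behaving
  extremely.

A single binary choice cannot distinguish the two. The countercurrent
apparatus can, because it gives each fly five consecutive chances to walk
towards the light and bins the group into six tubes by the number of
positive choices; repeating the session doubles the choices to ten.
`flychoice` implements the full analysis pipeline for these experiments
— the indices, the fractionation model, the walking-arena metrics that
control for general activity, and the statistics layer — together with a
seeded simulator so every stage is testable without laboratory data.

## Indices

For a T-maze session with $\#F_L$ flies in the bright tube, $\#F_D$ in
the dark tube, $\#F_E$ still in the (dark) elevator and $\#F_T$ total,
the Choice Index is

$$CI = \frac{\#F_L - 0.964\,(\#F_D + \#F_E)}{\#F_T},$$

where $0.964 = 1 - 0.036$ down-weights the dark-plus-elevator count by
the extra volume of darkness the elevator contributes. $CI = 1$ means all
flies chose the bright arm; $CI = -0.964$ means all preferred the dark.
`correction_factor()` exposes the multiplier, and
`choice_index(..., elevator_proportion = 0)` recovers the classic
uncorrected preference index. We apply the correction to *every* CI, not
only to pooled second sessions, because it is part of the index
definition; the uncorrected form remains one argument away.

For a countercurrent session with $\#F_k$ flies in tube $k$, the
Performance Index is the occupancy-weighted mean tube,

$$PI = \frac{\sum_{k=0}^{5} k\,\#F_k}{\#F_T} \in [0, 5].$$

When per-fly assignments are available, $PI$ equals the unweighted mean
of the per-fly tube indices exactly — a property the tests exploit.

Flies are sometimes lost between loading and scoring. By default the
denominator is the number of flies actually found (the formula is
silent about losses, and conditioning on recovery is the conservative
reading); `denominator = "nominal"` divides by the loaded count instead.

## The fractionation model

Order the five choices any way you like: the tube index is the number of
walks, so under a shared walk probability $p$ the tube occupancy is
$\mathrm{Binomial}(5, p)$, and under preferences $p_i \sim
\mathrm{Beta}(\alpha, \beta)$ it is beta-binomial,

$$\Pr(K = k) = \binom{5}{k}
  \frac{B(k + \alpha,\, 5 - k + \beta)}{B(\alpha, \beta)}.$$

`fit_tube_model()` fits either model to observed tube counts by maximum
likelihood under a multinomial likelihood and is the package's central
fitting function; the returned `tube_fit` object supports `coef()`,
`logLik()`, `AIC()`, `summary()`, `residuals()`, `plot()`, `simulate()`
and `predict()`. The binomial MLE is the closed form $\hat p = PI/5$;
the beta-binomial likelihood is maximised over log-shapes from the fixed
start $\alpha = \beta = 1$ (Nelder–Mead, relative tolerance $10^{-8}$),
which makes fits deterministic. Log-shapes beyond $\pm 30$ are rejected
inside the objective: past that point the likelihood is flat at the
binomial limit and the `lbeta` differences underflow, so the cap only
removes a numerically meaningless plateau. Fits whose shapes run to that
edge, and single-tube degenerate data, are flagged `boundary` rather
than raised as errors.

Model comparison uses AIC ($2k - 2\ell$, $k = 1$ or $2$).
`compare_tube_models()` also reports the likelihood-ratio statistic
against $\chi^2_1$, flagged approximate because the binomial lies on the
boundary of the beta-binomial parameter space.

The retest experiment has a closed-form prediction under the
individuality model: after observing $k$ walks in 5 choices, a fly's
posterior preference is $\mathrm{Beta}(\alpha + k, \beta + 5 - k)$, so
the expected second-session PI for the tube-$k$ subgroup is

$$E[PI_2 \mid k] = 5\,\frac{\alpha + k}{\alpha + \beta + 5},$$

strictly increasing in $k$ for finite shapes — while the binomial model
predicts the same value for every tube. `predict()` on a `tube_fit`
returns this curve. This model-based formalisation is an extension of
the qualitative fractionation argument: the heterogeneity account is
the only one estimated here, and within-session persistence (a fly that
just walked being more likely to walk again) would mimic it; the
apparatus cannot observe choice order within a tube, so the two cannot
be separated from tube counts alone.

## The synthetic-behavior generator

`population_model()` + `sample_flies()` draw fly populations under the
two accounts. Defaults encode the study conditions: mean preference 0.7
(the canonical 70/30 bright/dark split), groups of 80 flies, elevator
capture probability 0.05, pooling minimum 40 flies (half a standard
group), five choices per countercurrent session. The individuality
default uses concentration $\alpha + \beta = 4$, a broad preference
spread; any shapes can be supplied.

Activity — the latent locomotor level that scales walking speed in the
arena — is drawn from a normal distribution (mean 1, sd 0.3) truncated
at zero via its quantile function, with a Gaussian copula inducing a
correlation (default $\rho = 0.6$) with `p_light`: more photopositive
flies are more active. The truncated-normal/copula pair is the simplest
structure that reproduces a preference–activity correlation without
constraining either margin.

Design choices worth knowing:

* **Elevator capture** is an independent Bernoulli event before the
  choice; nothing in the assay suggests capture correlates with
  preference, and the model keeps it orthogonal by construction.
* **Traits are fixed across sessions.** The retest protocol re-runs the
  *same* trait rows, which is exactly what makes the individuality model
  history-dependent. Day-to-day drift is not modelled.
* **Walk link.** The countercurrent choice is asymmetric — walking
  versus staying — so a fly's general inclination to walk could
  contribute to its tube. The simulator offers
  `walk_link = "activity"`, where $P(\text{walk}) = p_i \cdot
  \min(a_i/\bar a, 1)$, to emulate that confound. The *default* is the
  pure-preference link ($s \equiv 1$): because activity is persistent
  and heterogeneous, the activity-scaled link induces history dependence
  even under a shared-$p$ population, which would blur the very
  spontaneity/individuality contrast the generator exists to exhibit.
  The closed-form binomial/beta-binomial occupancy laws also hold only
  under the pure link, so it is the analytically honest default.
* **Flies do not interact.** Choices are independent across flies even
  in a group; nothing in the group assays identifies interaction, and
  independence is the standard assumption the indices already make.

`simulate_retest()` chains first sessions, the pooling rules (bright
per replicate; dark+elevator merged across replicates until 40; tube
subgroups likewise) and seeded second sessions. Pools short of the
minimum are retested but flagged, never dropped. For the countercurrent
retest at realistic scale we default to 24 first sessions of 80 flies,
which yields on the order of eight 40-fly second-session pools per tube
under a uniform preference distribution — the desk-scale analogue of
the original protocol, which pooled across many more first sessions to
reach eight replicates per tube.

## The Buridan arena simulator and its metrics

The arena is a 117 mm round platform (moat-bounded) with two opposing
30 mm black stripes 148.5 mm from the centre. (The apparatus
description's "148.5 cm" is dimensionally impossible inside a 313 mm
cylinder; we read it as millimetres, and the geometry is configurable.)
Tracks are 900 s at 10 Hz.

`simulate_buridan()` uses discrete-time kinematics on the sampling grid:
the fly walks towards one stripe with per-frame heading jitter, flips to
the opposite stripe when it reaches the platform edge, and pauses at a
configurable rate with exponential pause durations. The per-frame step
is `base_speed * activity / sampling_rate`, so path length scales
linearly with the activity trait. This reproduces the *features the
metrics consume* — fixation, shuttling, pausing, speed — not real fly
locomotion: there is no thigmotaxis, no saccadic body turning, no
tracking noise. Passing tests on these tracks validates the metric
implementations and the qualitative activity–phototaxis coupling, not
any claim about real trajectories.

The eight metrics follow the standard tracker definitions:

| metric | definition | unit |
|---|---|---|
| activity time | (total − paused time)/total × 60 | s/min |
| pauses | pause count × 60/total | 1/min |
| distance | sum of inter-frame displacements | mm |
| median speed | median over moving frames ≤ 50 mm/s | mm/s |
| pause duration | median pause length | s |
| walks | alternating stripe-zone entries × 60/total | 1/min |
| stripe deviation | median of the smaller fly→stripe angle | degrees |
| meander | median of turn angle / speed | deg·s/mm |

Numerical choices the definitions leave open:

* **Movement threshold.** "No movement" needs a displacement epsilon;
  we use 0.1 mm per frame (1 mm/s at 10 Hz), below plausible tracking
  noise, configurable everywhere.
* **Pauses** are runs of non-moving frames strictly longer than 1 s;
  a 0.9 s rest is activity.
* **Jump filter.** Frames above 50 mm/s are excluded from the *median
  speed only*; they still count towards distance, since the exclusion is
  defined for the speed statistic.
* **Stripe-approach zone** (for walk counting) is not part of the
  published definitions: we use the sector within ±30° of a stripe
  bearing intersected with the outer 20% annulus of the platform, on the
  reasoning that a stripe-to-stripe walk must terminate near the edge
  facing a stripe. Both knobs are arguments.
* **Stripe deviation** is computed over moving frames only, and all
  angular outputs are degrees (the meander unit fixes that convention).
* **Missing values.** A fly that never pauses has no pause-duration
  median; a fly that never moves has no speed, deviation or meander.
  These are `NA`, never 0, so downstream rank tests are not biased by
  sentinel zeros.

Every metric is cross-checked in the test suite against an independent
brute-force single-pass implementation on randomized tracks (relative
tolerance $10^{-9}$), and all metrics are invariant under rigid rotation
of track and arena together.

## The statistics layer

The experimental comparisons are nonparametric throughout:
`kruskal_wallis()` (tie-corrected H, $\chi^2_{k-1}$ reference) with
`dunn_posthoc()` on the joint mid-ranks (tie-corrected, unadjusted and
Bonferroni p-values both reported — the omnibus-plus-rank-post-hoc
pairing is the standard companion). Normality and variance homogeneity
checks wrap `stats::shapiro.test()` and `car::leveneTest()`; Levene
centering defaults to the median (Brown–Forsythe), the robust choice
when the flavour is unspecified. The significance threshold is a single
configured value, default $p < 0.005$.

`pca_correlation()` standardises variables, eigendecomposes the
correlation matrix, and retains components with eigenvalue ≥ 1.
Loadings are reported in the correlation convention
(eigenvector × $\sqrt{\lambda}$), with raw eigenvectors alongside,
because "loading" is ambiguous across software and the correlation
convention is what makes a loading interpretable as a variable–component
correlation. Component signs are fixed deterministically (largest
loading positive).

## The analysis battery

`reproduce_analyses()` chains everything: group-size CI comparison with
Levene's variance test, repeated-day stability, both retest protocols,
binomial/beta-binomial fits with AIC comparison and the predicted retest
curve, per-tube Buridan metrics with Kruskal–Wallis across tubes, and
the PCA of light choices plus the eight metrics. With the default
individuality model the battery shows the expected structure: retest PI
rising with first-session tube, beta-binomial preferred by AIC, the
locomotor metrics (distance, walks, activity time, speed) varying across
tubes, and light choices co-loading with distance and walks on the first
component.

Default problem sizes — 15 sessions per group size, 8 T-maze and 24
countercurrent first sessions, 13 flies per tube at 900 s in the arena —
were chosen to mirror a realistic experimental campaign at a scale a
laptop reproduces in seconds; the test suite uses smaller tracks where
only correctness, not power, is at stake.

```{r battery, eval = FALSE}
rep <- reproduce_analyses(seed = 1, out_dir = "flychoice-report")
rep
```

Every report directory is self-describing: the resolved configuration
and seed are written next to the tables, and re-running from them
reproduces all numbers exactly.

## Limitations

* The generators formalise *between-fly heterogeneity* only. Real
  sources of the fractionation signal could include within-session
  persistence or state drift; tube counts cannot distinguish them, and
  the package does not try.
* The arena simulator is a caricature built for metric validation (see
  above); quantitative agreement with real tracks is out of scope.
* The 24 h retest-interval effect is not modelled; retest intervals are
  metadata only.
* Reported headline statistics from real datasets (specific H values,
  loadings) depend on raw data that are not available; the package
  reproduces the *structure* of those analyses on synthetic data, not
  their numbers.
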