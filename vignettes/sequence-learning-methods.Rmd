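---
title: "Models and methods: information-theoretic analysis of SRT sequence learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: information-theoretic analysis of SRT sequence learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(srtlearn)
```

## The scientific question

In the serial reaction time (SRT) task a target appears at one of four
horizontal locations ("a" to "d"); the subject presses the matching key and
the reaction time (RT) from stimulus onset to key press is recorded. When
the sequence of locations carries statistical structure, RTs fall with
predictability. Two questions organise the analyses this package
implements:

1. **Shape** — is the RT/uncertainty relationship linear (as a literal
   reading of Hick's law suggests) or sigmoid (as psychometric functions
   generally are)?
2. **Predictor** — is performance tracked better by *conditional*
   statistics of the sequence (probability or entropy of the next location
   given the recent past, the quantity a closed-loop, on-line prediction
   strategy would use) or by *joint* statistics (probability or entropy of
   whole transitions, the quantity an open-loop, chunk-execution strategy
   would use)?

## Transition sets and the four predictors

A sequence of locations is summarised by its set of *transitions*: windows
of `n_prev` previous locations plus the present one, counted circularly
over the nominal repeating sequence (the training sequence repeats block
after block, so its structure wraps around). For the eight-location cycle
`ababcdcd` at one previous location the eight windows yield six distinct
transitions:

```{r}
predictor_table(location_sequence("ababcdcd"), n_prev = 1)
```

Four predictors are derived from the counts:

* **JP**, joint probability: count of a transition over the total count.
* **CP**, conditional probability: JP over the summed JP of transitions
  sharing the same previous-location prefix — the probability of the
  present location given its history.
* **JE**, joint entropy: $-\sum_g \mathrm{JP}(g)\log_2 \mathrm{JP}(g)$, in
  bits; uncertainty of the whole transition set.
* **CE**, conditional entropy: $-\sum_g \mathrm{JP}(g)\log_2
  \mathrm{CP}(g)$; uncertainty of the present location once the history is
  known. By the chain rule it equals JE minus the entropy of the prefix
  marginal, an identity the test suite checks to $10^{-9}$.

Entropies are reported in bits (base 2); the base is a convention and only
rescales values. Zero-probability transitions are omitted from all tables,
so $0\log 0$ never arises. Realized trial streams get per-trial JP/CP by
looking their gram up in the nominal table of the generating sequence;
grams that the nominal table lacks (possible in random or probabilistic
streams) fall back to the empirical table of the realized trained-block
stream, so random-sequence trials also carry predictors.

## Sequence generators

Three generator kinds cover the designs analysed here:

* `gen_random_norepeat()` — uniformly random subject to the task's one
  restriction, no immediate repeat. At one previous location its transition
  set tends to 12 equiprobable grams, JE $\to \log_2 12 \approx 3.585$
  bits.
* `gen_repetitive()` — deterministic cycles (CE $= 0$ whenever every
  prefix in the cycle is unique).
* `gen_probabilistic()` — first-order Markov chains with zero diagonal.

`sequence_presets()` ships six named sequences — random, complex/simple
probabilistic, complex/simple/very-simple repetitive — whose one-step joint
entropies are strictly ordered (2.0, 2.5, 3.0, 3.18, 3.44, 3.585 bits),
mirroring the ordering of asymptotic group RTs in the six-group design.
Only this ordering, not the literal identity of the training cycles,
drives any downstream analysis. Whether the probabilistic sequences of the
original design carried longer-range dependencies is not documented;
presets are first-order Markov, with the transition-matrix interface as
the extension point.

`gen_entropy_graded_family()` emulates a multi-session design in which
every session trains a different sequence spanning a wide entropy range.
Each target JE is met by mixing a deterministic base cycle toward the
uniform no-repeat chain: with probability $\varepsilon$ the structured
successor is replaced by a uniform alternative. The mixing weight is
solved by bisection against the *exact* gram entropy of the resulting
Markov chain (computed from its stationary distribution), so achieved
entropies are deterministic, exactly monotone in the target, and
accurate to $10^{-4}$ bits wherever the target is attainable;
out-of-range targets are flagged per sequence rather than raised as
errors. The base-cycle pool ("ab", "abc", "abcd", "ababcd", "ababcdcd",
"abacdbdc") deliberately varies alphabet coverage and cycle length so
that CE is not simply a shifted copy of JE across the family — without
that variation the JE-versus-CE model comparison would be degenerate by
construction.

## The synthetic RT model

Human data for these designs are available only on request, so the
package ships a generator that produces data *with the statistical
structure the analysis assumes*, used for end-to-end validation and
parameter-recovery studies:

$$\mathrm{RT}_i = \mathrm{sigmoid}(x_i;\ X_{half}, Y_{max}, Y_{min},
\mathrm{slope}) \times \epsilon_i, \qquad \epsilon_i \sim
\mathrm{logNormal}(0, \sigma)$$

* The sigmoid is the four-parameter logistic of `sigmoid_rt()`, increasing
  in entropy predictors and mirrored (decreasing) in probability
  predictors. The original report prints the fitted parameters but not the
  equation itself; the logistic parameterisation here, with orientation
  chosen per predictor, is this package's declared form, and whether
  probabilities should be log-transformed before fitting is left as an
  explicit option for the analyst rather than assumed.
* Noise is multiplicative lognormal with $\sigma = 0.25$ (right-skewed
  RTs; the lognormal with median 1 leaves medians — the summary statistic
  used throughout — unbiased). No distributional family for RT noise is
  documented for the original data; lognormal is a modelling choice.
* Errors are independent Bernoulli lapses at 3% per trial; error trials
  are excluded from RT modelling downstream. Stimulus re-presentation
  after an error is not simulated.
* RTs are capped at the 3000 ms response deadline.

A session is 25 blocks of 49 trials (1225 trials): blocks 1–4 and 23–25
run the random sequence, blocks 5–22 the session's own sequence. Learning
across the trained blocks is an exponential relaxation of the sigmoid
parameters (`learning_trajectory()`): $X_{half}$ drifts up (more of the
uncertainty range becomes well predicted), $Y_{min}$ drifts down (simple
sequences become automatic), $Y_{max}$ stays near-flat (the
stimulus–response mapping itself is learned before training begins). The
default drift — $X_{half}$ 2.2 → 5.2 bits, $Y_{min}$ 350 → 225 ms,
$Y_{max}$ 480 → 470 ms at rate 0.15 per block — was fixed once, to
represent clear progressive learning whose signatures remain identifiable
in block-wise fits at the 48-session scale, and is expressed on the
three-previous-location entropy scale (below).

Two generating predictors mirror the two levels of analysis: per-trial JP
(decreasing orientation) produces trial-level dispersion for the six-group
design; sequence-level JE (increasing orientation) drives whole sessions
for the multi-session design.

## History length: why entropy analyses default to three previous locations

The trial-level analyses of the original report compute probabilities with
three previous locations, and its entropy analyses follow suit. That
choice matters numerically: at one previous location JE spans only
$[1, 3.585]$ bits across attainable sequences, while the slope-1 sigmoid
used for block-wise fits has a dynamic range of roughly 4–5 bits — both
asymptotes would be extrapolations and the fits ill-identified. At three
previous locations JE spans roughly $[1, 6.75]$ bits, placing both
asymptotes inside the data. Entropy-based generation, the block-wise
fits and the pipeline therefore default to `n_prev = 3`; comparison
grids always sweep `n_prev` 1–4.

## Fitting and model comparison

* `fit_linear()` is ordinary least squares via `lm()`.
* `fit_sigmoid()` is Levenberg–Marquardt nonlinear least squares
  (minpack.lm) over the logistic, with starts from the data (asymptotes at
  the 5th/95th RT percentiles, midpoint at the x median, width a sixth of
  the x range), five deterministic jittered restarts, best residual sum of
  squares winning and ties broken by first found. Any parameter can be
  held fixed; fixing the slope at 1 is the standard stabilisation for
  block-wise fits. Standard errors come from the Jacobian at the optimum.
  Non-convergence from every start is flagged, never silently reported;
  constant-`y` and zero-x-range inputs are flagged as degenerate.
* $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ for both families — comparable
  across linear and sigmoid fits, and allowed to go negative for fits
  worse than the mean. When TSS is zero (constant response) $R^2$ is
  reported as 0: a fit of a constant explains nothing.

`compare_predictors_trialwise()` fits single-trial RT against JP and CP,
linear and sigmoid, for each history length 1–4, pooled over units inside
the analysis window — trials 442–1078, i.e. blocks 10–22, chosen to avoid
the fast-changing RTs of early training. Any display subsampling in the
plot helpers affects plotting only; fits always use every point.
`compare_predictors_sessionwise()` does the same with one median RT per
unit against JE and CE. `blockwise_sigmoid()` fits, per training block,
the median RT of every unit against its sequence's JE with the slope
fixed at 1, yielding $X_{half}/Y_{max}/Y_{min} \pm$ SE trajectories;
non-converging blocks are flagged and excluded.

One structural fact discovered in validation is worth knowing: when the
stationary location usage is uniform (as it is for all presets), CP is
exactly $4 \times$ JP at one previous location, and both fitted families
are invariant to a rescaling of x — so the (JP, sigmoid) and (CP, sigmoid)
cells tie to numerical precision there. The tie is real, not a defect;
with longer histories the two predictors decouple.

## What the synthetic validation does and does not show

The test suite checks, at the scale of the emulated designs (48 units,
1225 trials each): that the grid's best cell is (JE, sigmoid) in at least
95 of 100 replicate experiments generated from a sigmoid of JE; that
$\{X_{half}, Y_{max}, Y_{min}\}$ are recovered with bias under 5% with the
slope fixed at 1; and that block-wise trajectories recover a monotone
$X_{half}$ rise and $Y_{min}$ fall (median Spearman rank correlation with
block beyond $\pm 0.9$ over five replicate experiments — a single
18-point rank correlation is itself a noisy statistic). These are
*self-consistency and recovery* results: they show the estimators detect
and quantify the structure the generator puts in, at realistic noise
levels. They cannot show that human RTs follow a sigmoid of joint
entropy — that claim belongs to the original behavioural data, which the
generator emulates only in its published design constants and qualitative
dynamics. Features of real data the generator does not attempt:
sequential autocorrelation of RT noise, post-error slowing, fatigue,
reversal/hand-transition effects, and any regularity not expressible in
fixed-length transitions.

## Numerical choices and degenerate inputs

* Entropy normalisation tolerance $10^{-9}$ on input distributions;
  chain-rule identity tested at $10^{-9}$; probability tables exact to
  machine precision.
* Gram tables are emitted in lexicographic order for reproducible
  serialisation.
* Sequences shorter than `n_prev + 1`, symbols outside the alphabet,
  non-stochastic transition matrices (tolerance $10^{-9}$) and empty
  transition sets are errors; unattainable entropy targets are flagged,
  not fatal.
* All simulation entry points take a `seed` and leave the global RNG state
  untouched when one is supplied; identical seeds give bit-identical
  outputs.
* Deterministic cycles shorter than the transition window are tiled by
  whole cycles before circular counting, which leaves the transition
  distribution unchanged.

## Problem sizes

The shipped validation uses the full design constants of the emulated
experiments (6 × 8 subjects or 48 sessions, 25 × 49 trials) for
single-run checks; the replicate-based recovery studies run 100
experiment replicates for the grid and bias checks and five for the
block-wise trajectory check. The heavier pipeline examples in tests run
reduced unit counts (12–24 sessions) — enough for every fit to be
well-posed — to keep the default check fast.
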