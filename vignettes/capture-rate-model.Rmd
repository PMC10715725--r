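---
title: "The capture-rate model and the vigor analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The capture-rate model and the vigor analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foragekit)
```

## The model

A forager alternates between *work* — a run of $n_s$ visually guided
saccade trials, each succeeding with probability $\beta_s$ and adding a
food increment of value $\alpha$ to a cache — and *harvest* — a bout of
$n_l$ licks, each succeeding with probability $\beta_l$, that consumes
the cache. The normative hypothesis is that both the decision (how long
to work) and the movements' vigor (how fast to lick) are chosen to
maximize the **capture rate**, the net utility per unit time:

$$J(n_s, n_l) \;=\; \frac{\alpha\,\beta_s\, n_s \left(1 -
\frac{1}{1+\beta_l n_l}\right) \;-\; n_l\, c_l \;-\; n_s^2\, c_s}
{n_l T_l + n_s T_s}.$$

The hyperbolic term is the harvested fraction of the cache: early licks
deplete a full tube and are worth more than late ones. The work effort
$c_s n_s^2$ grows *faster than linearly* with the number of trials —
the assumption that makes an interior optimum exist at all: without it,
the best policy would be to work forever.

Licking vigor enters through the per-lick effort. The energetic cost of
a single lick aimed at a tube at distance $d$ with duration $T_l$ is
taken, like reaching and walking costs, to be concave upward in
duration:

$$c_l(T_l) = \frac{d^2}{T_l} + k\,T_l,$$

minimized at $T_l = d/\sqrt{k}$ (linear in distance at fixed $k$).
Substituting $c_l(T_l)$ into $J$ makes the optimal policy a triple
$(n_s^*, n_l^*, T_l^*)$: how long to work, how many licks to harvest,
and how vigorous each lick should be.

`optimal_policy_fixed_cost()` and `optimal_policy_with_distance()`
solve the two problems; `sweep_policy()` produces the comparative
statics. The model's qualitative predictions, all reproduced by the
test suite:

* a higher lick cost (a farther tube) lengthens the optimal work period
  ($n_s^* \uparrow$), shortens the harvest ($n_l^* \downarrow$), slows
  the licks ($T_l^* \uparrow$, superlinearly in $d$), and lowers the
  achievable capture rate;
* the capture-rate-maximizing lick duration is always *shorter* than
  the energetically optimal one, $T_l^* < d/\sqrt{k}$: it pays to move
  vigorously to get reward sooner;
* a higher reward value $\alpha$ (hunger) promotes work **and** lick
  vigor — the signature that separates this additive utility from a
  multiplicative one, $J(T) = \alpha / \left[(1+T)\,U(T)\right]$
  (`multiplicative_optimal_duration()`), whose optimal duration is
  invariant to $\alpha$ because reward merely scales the utility.

### Solvers and numerical choices

Two solution modes are provided and cross-checked. The **integer grid**
(default) enumerates $n_s \in [1, 15]$, $n_l \in [0, 60]$ — bounds that
comfortably bracket every parameterization we exercise, with boundary
hits warned about — optimizing $T_l \in [0.01, 10]$ by golden-section
search for each candidate in the distance problem. Ties within
$10^{-12}$ break toward the smallest $n_s$, then $n_l$. The
**continuous relaxation** polishes a coarse-grid argmax with bounded
quasi-Newton ascent from multiple starts and accepts the result only if
it is an interior stationary point (central-difference gradient below
$10^{-2}$ relative) that beats every boundary value; otherwise the
problem is flagged infeasible rather than erroring. $n_l = 0$ is
admitted (harvest start, negative rate), $n_s = 0$ is not: a work
period is by definition at least one trial, and the time denominator
must stay positive. The first-order condition in $n_s$ has the closed
form exposed as `stationary_ns()`; the quadratic's positive root grows
as $\sqrt{c_l}$ once the lick-cost term dominates, which is the sense
in which optimal work tracks the square root of the cost of licking.
Over moderate cost ranges the *joint* optimum grows considerably more
slowly (the harvest policy re-equilibrates as $c_l$ rises), a tension
the acceptance suite measures rather than hides.

The caption and methods parameterizations of the high-effort condition
differ ($c_l = 2$ vs. $2.5$); both give the same optimal work period of
five trials, and both are exercised in the tests.

## Vigor

A movement of amplitude $x$ has an expected peak speed on the
subject's **main sequence**,

$$v(x) = a\left(1 - \frac{1}{1 + b\,x}\right),$$

fitted per subject and movement type across sessions
(`fit_main_sequence()`, Levenberg–Marquardt with optional Huber-style
reweighting for heavy-tailed peak speeds). **Vigor** is the ratio of a
movement's actual peak speed to this expectation
(`compute_vigor()`): vigor 1.10 means 10% faster than typical for that
amplitude, and the measure is invariant to any common rescaling of
speeds. Cross-condition vigor contrasts must reference a main sequence
pooled across the sessions being compared; a per-session fit absorbs
exactly the gain under study.

Saccades are detected from the gaze trace by a speed threshold with
hysteresis (onset 50 deg/s, offset 30 deg/s, minimum duration 10 ms,
merge gap 20 ms; Savitzky–Golay smoothing, window 7 samples at 1 kHz).
These thresholds are conventional rather than prescribed, and all are
configurable. A saccade succeeds when it lands within the criterion
radius of its target — 1.25 deg by default, with the alternative
1.5 deg criterion available as a parameter, since both conventions
appear in practice. Licks are classified geometrically from the
tongue-tip trajectory apex against the 4.4 mm tube aperture
(`classify_lick()`): inner-tube, outer-edge, under-tube, or grooming,
with protraction and retraction peak speeds measured on either side of
the apex.

## Session analysis

`segment_periods()` re-derives work/harvest structure from the event
stream alone: a harvest starts at the first reward-seeking lick after
at least one trial and ends at the next trial's center-target saccade
or an inter-lick gap above the bout threshold. The 500 ms default gap
follows from a typical ~3 Hz lick rhythm (~330 ms intervals); sessions
that open mid-harvest yield a flagged partial period that summaries
exclude. Pupil area is averaged in a ±250 ms window locked to each
reward-relevant saccade onset and each lick (anchored at the moment of
peak tongue displacement by default, with onset anchoring available —
the two conventions differ by tens of milliseconds), then z-scored
against that session's distribution of such measures, making the
measure invariant to affine changes in the raw trace. Binned summaries
(`binned_relation()`, bin width 0.05 vigor units, bins under 10 events
dropped — an invented, configurable floor) and Pearson correlations of
bin means connect vigor to pupil, trial number, and endpoint accuracy;
`conditional_vigor_change()` contrasts lick-to-lick vigor changes after
successful versus failed licks.

A caveat the tests make explicit: under the null (no coupling), the
correlation of ~10–15 bin *means* is itself noisy (SD
$\approx 1/\sqrt{n_{\text{bins}}-1}$), so the "no coupling" check is
run on a fixed, documented fixture rather than asserted as a universal
property.

## The synthetic generator

`generate_session()` emulates the statistical structure of the
recorded sessions, not any particular animal: alternating cycles with
attempted trials drawn around 8.5 per work period (SD 1.5, clamped to
3–14) and successes i.i.d. Bernoulli($\beta_s = 0.5$) — matching
roughly eight attempts with four to five successes — and harvests of
about 17 licks (SD 2) with contacts i.i.d. Bernoulli($\beta_l = 0.30$).
Kinematics are drawn from the configured main sequences with
multiplicative lognormal speed noise (sdlog 0.10; speeds stay
positive); endpoint errors are Gaussian with an SD that decreases with
vigor. Within-period vigor dynamics are piecewise: a linear per-trial
decline during work (1% per trial from 1.05) and a fast three-lick
rise then slow decline during harvest — shapes chosen qualitatively,
with magnitudes as free configuration, not claims. After each food
contact the lick-vigor level steps up by `reinforcement_delta` (0.03)
and stays up for the bout, so the post-success minus post-failure
contrast recovers the increment directly. Pupil is affine in the
current movement's vigor with one latent gain shared by saccades and
licks plus white noise, written as a ±150 ms plateau per event so that
neighboring events' windows do not contaminate each other. The
independence assumptions (Bernoulli successes, white pupil noise, no
slow drifts or shared session states) are exactly what real sessions
will violate; passing recovery tests therefore demonstrates that the
pipeline's estimators are unbiased on data that satisfies the model,
not that the model fits any animal.

`make_fixture_suite()` freezes the recovery scenarios (coupling on,
coupling off, near/mid/far tube with built-in work-length and
lick-vigor contrasts, a zero-lick session) from one base seed; the
test suite uses base seed 101 with 120 cycles for the coupling
fixtures (roughly 2,000 licks, enough for ~12 vigor bins) and 20
cycles elsewhere, sizes at which the whole suite runs in a few
minutes.

## Worked example

```{r example, eval = FALSE}
p <- policy_params(alpha = 20, beta_s = 0.5, beta_l = 0.3,
                   c_s = 0.5, T_s = 1, T_l = 0.2, c_l = 0.5)
optimal_policy_fixed_cost(p)
#> <policy_solution>
#>   n_s* = 4, n_l* = 8
#>   capture rate J* = 2.89916  [integer_grid]

s <- generate_session(generator_config(seed = 11, n_cycles = 30))
res <- run_pipeline(s)
res$correlations
```

## Known limitations

The capture rate describes a single work–harvest cycle, not a sequence
of cycles or a session-long budget; there is no tube-capacity
constraint (which would penalize working far beyond the tube's
capacity) and no stochastic dynamic programming over states. The
continuous solver certifies stationarity and boundary dominance, not
global optimality — the fine-grid oracle in the tests covers that. The
generator makes no attempt to model slow arousal drifts, shared
between-session states, or tracking noise; conclusions about real
recordings need the real recordings.
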