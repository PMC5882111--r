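---
title: "Decision-making with the recursive MSPRT: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-making with the recursive MSPRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmsprt)
```

## The model

The multi-hypothesis sequential probability ratio test (MSPRT) chooses among
$N$ hypotheses by accumulating evidence until one posterior probability
crosses a threshold. This package implements its recursive generalization,
the rMSPRT, in which the posterior computed $\Delta$ time steps in the past
is fed back as the prior for the present update — the natural description of
a decision variable circulating around the cortico-basal-ganglia-thalamo-
cortical loop with a total latency of $\Delta$ steps.

Evidence arrives as $C = N$ parallel streams of inter-spike intervals (ISIs)
with the statistics of macaque MT neurons during the random dot motion task.
ISIs are modelled as lognormal; the channel matching the true motion
direction draws from the *preferred* distribution $f_*$ (shorter mean ISI)
and all others from the *null* distribution $f_0$. The packaged registry
(`load_parameter_table()`) carries the per-coherence means and standard
deviations of both channels: the measured set $\Omega$, and two
information-depleted sets $\Omega_d$ (one per task variant, $N=2,4$) in
which the null channel has been moved towards the preferred one.

Writing $\kappa = \log\mu - \Theta^2/2$ and
$\Theta^2 = \log(\sigma^2/\mu^2 + 1)$ for the moment-matched lognormal
shape, the per-observation log density ratio is a quadratic in $\log x$
with coefficients $g_0, g_1, g_2$ (`likelihood_coefficients()`). Only
$g_1$ and $g_2$ enter inference: the $g_0$ terms are identical across
hypotheses and cancel in the posterior normalization, as does any additive
hypothesis-independent baseline $c(t)$. In the negative-log domain the
update is

$$-\log P_i(t) = -z_i(t) - \log \pi_i(t) +
  \log\textstyle\sum_j \exp\!\big(z_j(t) + \log \pi_j(t)\big),$$

where $z_i = y_i + c$, $y_i$ is the simplified log-likelihood summed over
the active window (all observations while $t \le \Delta$; the last
$\Delta$ observations afterwards), and $\pi_i$ is the flat initial prior
while $t \le \Delta$ and the fed-back posterior $P_i(t-\Delta)$ afterwards.
A decision fires when $\min_i -\log P_i(t) \le \theta$ with
$\theta \in (0, \log N]$.

Because recursive and single-shot Bayes give identical posteriors, the
rMSPRT, the non-recursive MSPRT, and a batch computation over the full
history coincide to floating-point accuracy; for $N = 2$ the difference of
negative log-posteriors is exactly Wald's cumulative log-likelihood-ratio
statistic. These identities are asserted in the test suite at $10^{-10}$.

## Circuit mapping

Each update decomposes onto the loop (all latencies default to one step,
$\Delta = \delta_{yb}+\delta_{bu}+\delta_{uy} = 3$):

* **sensorimotor cortex** (LIP/FEF): $z_i(t)$ plus the fed-back log-prior
  term — the likelihood of each alternative plus bias;
* **striatum**: a copy of the cortical signal (relay assumption);
* **basal-ganglia output** (SNr): the fresh negative log-posteriors — the
  decision variables tested against $\theta$;
* **thalamus**: the delayed posterior returning to cortex, plus the
  diffuse cortico-thalamic baseline $h(t)$.

The baselines are $c(t) = h(t-\Delta) + l$ and
$h(t-\delta_{bu}) = \tfrac{w_{yu}}{N}\sum_i [z_i(\cdot) + \log P_i(\cdot)]$
with defaults $l = 15$ and $w_{yu} = 0.4$ ($w_{yu} < 1$ keeps the positive
cortico-thalamo-cortical feedback bounded). Together with the data scaling
factor $n = 40$ (which divides the raw ISIs and makes the simplified
log-likelihoods positive without touching inference), these three free
parameters shape the displayed dynamics only; the test suite asserts
posterior invariance under all of them.

The display convention adopted here counts observations from
step 0 and prepends a pre-evidence step $-1$ at which cortex shows
$l + \log \pi_i$ and the basal-ganglia output $-\log \pi_i = \log N$. The
feedforward phase is then steps $0..\Delta-1$ and the fed-back posterior
first reaches cortex at step $\Delta$ — the *fork* after the initial
*ramp*. The exact linear combinations plotted as "model LIP" and "model
thalamus" are a documented judgment call (the mapping literature describes
the decomposition verbally, not as printed formulas); the basal-ganglia output, in contrast, is the inference variable
itself and is reproduced exactly.

## Behaviour and the information account

A trial's decision sample size $T$ converts to continuous time through the
mean ISI of the channel that drove the choice:
$\tau_c = (\langle T\rangle_c + 0.5)\,\mu_* n$ on correct trials and
$\tau_e = (\langle T\rangle_e + 0.5)\,\mu_0 n$ on errors (the half ISI is
the expected wait from decision initiation to the first spike). Reaction
times add a non-decision time, defaulting to 250 ms with 200–300 ms as the
macaque-plausible band. Thresholds are calibrated per condition to an
exponential psychometric target,
$\epsilon = 0.50 e^{-0.11 s}$ ($N=2$) and $0.75 e^{-0.08 s}$ ($N=4$) for
coherence $s$ in percent.

The information account rests on the Wald-style relation that the mean
total discrimination information consumed at fixed error rate and $N$ is
approximately constant: $\hat I = \langle T\rangle_c K$, with $K$ the
Kullback–Leibler divergence (bits per ISI) from $f_*$ to $f_0$. Dividing
$\hat I$ by a subject's implied sample size
$(\bar{\mathrm{RT}} - t_{nd})/\mu_* n - 0.5$ gives the per-ISI information
the subject actually used, $\hat K^m$, and the percentage lost. *Depletion*
(`deplete_information()`) then shrinks the null channel towards the
preferred one by a common proportion of both moments until the pair carries
exactly $\hat K^m$, solved by bisection to $10^{-9}$ bits.

Because $\hat I$ inherits an upper-bound flavour from the underlying
inequality, the first-pass $\hat K^m$ over-estimates the information used,
most visibly where decisions take few steps. The *enhanced-match*
correction removes this empirically: simulate the model on the recovered
statistics, multiply $\hat K^m$ by the ratio of model to subject decision
time, and re-deplete. `recover_information_loss()` iterates this to a
fixed point; since the recovered sets live in the one-parameter depletion
family, the fixed point is the statistics whose simulated reaction times
match the behavioural table.

## The synthetic behavioural fixture

No subject-level reaction-time tables ship with the package (none are
publicly distributed for these experiments), so `generate_fixture()` manufactures one: it depletes $\Omega$ by a
fixed information-loss fraction (default 0.6, the scale of the losses the
estimation pipeline reports), simulates the rMSPRT on that *secret* set at
the calibrated error-rate targets, and converts the mean sample sizes to
reaction times with 250 ms of non-decision time. The secret sets ride
along as attributes so that the full pipeline can be closed: recovering
the secret per-condition divergences from nothing but the fixture's
reaction times is the package's strongest end-to-end test (it closes
within ~4% relative).

What the fixture emulates is the *mean* behaviour of an information-lossy
observer with the model's exact generative structure. It does not emulate
sequential dependencies, lapses, non-stationary vigilance, non-decision
time variability, or any mismatch between the subject's likelihoods and
the true generative statistics — so passing the recovery test shows the
pipeline is self-consistent, not that real subjects satisfy its
assumptions.

## Numerical choices

* **Log-domain arithmetic.** All posterior algebra uses negative logs with
  a max-shifted log-sum-exp; posteriors would underflow within a few steps
  otherwise.
* **Seeding.** One root seed; every trial and evidence chunk derives a
  counter-based child seed, so any single trial of a batch is reproducible
  in isolation and batch and single-trial runs are bit-identical. Ties at
  the arg-min (measure-zero under continuous evidence) are broken
  uniformly with a dedicated child seed.
* **Threshold calibration.** The error rate is monotone in $\theta$, and a
  single lockstep simulation evaluates the whole error-rate curve on a
  140-point log-spaced threshold grid (each trial records the choice it
  would have made at every level on its way down); the calibrated
  $\theta$ is read off by monotone interpolation. All levels share the
  same evidence streams, so the only residual is the binomial sampling
  error of the calibration sample. Simulation studies in this package use
  calibration samples of 10000–20000 trials.
* **Paired pipeline runs.** Decision times are steeply sensitive to the
  achieved error rate near chance, which makes independently seeded
  fixture and recovery runs noisy in ratio. Both sides of the pipeline
  therefore key their child seeds on a canonical condition index: runs of
  the same condition share evidence streams, and the decision-time ratio
  in the enhanced-match correction becomes a paired comparison (standard
  common-random-numbers practice).
* **Step cap.** Trials abort with a diagnostic error after $10^5$ steps;
  this guards information-free parameter sets, for which the posterior
  never moves.
* **Smoothing and windows.** Firing-rate summaries use a 20 ms window
  sliding every 1 ms over bins fully covered by data; Gaussian smoothing
  uses a unit-sum kernel truncated at 4 SD (mass loss below $10^{-4}$) and
  renormalized at the edges so constants pass through unchanged.
* **Problem sizes.** Acceptance-grade simulations use the standard
  protocol sizes: 3200/4800 total trials for the behavioural grids,
  10000 trials per condition for calibration closure and the recovery
  pipeline, 400–800 traced trials for the averaged circuit displays, and
  1000 trials for the continuous-time consistency check, which is run at
  the slowest condition where renewal edge effects (about
  $(1-\sigma^2/\mu^2)/2$ of an ISI) are smallest relative to the mean
  sample size.

## Known limitations

* The registry is treated as ground truth; estimating ISI statistics from
  raw recordings, alternative ISI families, correlated channels, and
  $C > N$ likelihood structures are out of scope.
* The psychometric calibration coefficients are taken as given, not
  refitted.
* Trace magnitudes are in arbitrary units; only their qualitative
  structure (ramp, fork, peak lag, baseline shifts with $N$) is asserted.
* The Wald-style account follows the field convention of a single-channel
  $K$; as a strict per-step bound on sample sizes one must use the
  symmetrized divergence of the full observation vector (the property
  tests do), but the account's ratios are insensitive to the convention
  because it appears on both sides.

## A worked example

```{r example, eval = FALSE}
registry <- load_parameter_table()
cond <- decision_condition(2, 25.6, "Omega_d")
theta <- calibrate_threshold(cond, error_rate_target(25.6, 2),
                             mc_trials = 10000, seed = 1)
trials <- run_trials(cond, as.numeric(theta), 5000, seed = 2)
mean(!trials$correct)                     # ~ the 2.99% target
st <- isi_stats(registry$Omega_d_N2, 25.6)
mean_decision_time_correct(mean(trials$T[trials$correct]),
                           st$preferred$mean_isi) + 250  # mean RT, ms
```
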