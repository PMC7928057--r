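---
title: "Models and methods behind skinstretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind skinstretch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinstretch)
```

skinstretch simulates a two-motor, force-controlled facial skin-stretch
stimulator and implements its complete evaluation pipeline: verification
of the delivered inter-channel time lags, and the temporal-order-judgement
(TOJ) psychophysics run on top of the device. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data experiments do and do not establish.

## The stimulus

The stimulus on each channel is a single raised-cosine force bump

$$F(t) = \tfrac{P}{2}\,\bigl(1 - \cos 2\pi f t\bigr), \qquad t \in [0, 1/f],$$

with $f = 6$ Hz and peak $P = 2$ N by default, i.e. about 167 ms long.
"Sinusoidal pulse" is ambiguous between a full sine cycle and a
non-negative bump; a full cycle would require pushing the skin, which a
wire-and-tab coupling cannot do, so the raised cosine — non-negative,
one period long, sinusoidal in shape — is the only physically admissible
reading, and the package enforces `force >= 0` throughout
(`inverse_motor_model()` rejects negative force requests).

Pulse pairs are placed on a common time base with a signed lag:
positive lag means the vertical channel leads. Lags are realised as
integer sample shifts at the 100 Hz control rate, so the design's
$\pm 10$ ms conditions are exactly one control-loop sample — the loop
rate is what defines the device's 10 ms timing precision. The default
padding (200 ms pre-silence, 300 ms post) absorbs the largest design lag
(120 ms) with margin; the physical inter-trial timing is not modelled.
The standard design crosses the 14 lags
$\{-120,\dots,-10, 10,\dots,120\}$ ms with 15 repetitions in a seeded
uniform random permutation (210 trials). No constraint beyond uniform
shuffling is imposed, since the design only requires "pseudo-random"
order.

## The force-control loop

Force control works through motor current: the electromagnetic relation
$F = k_f\, i$ (with $k_f$ the torque constant over the pulley radius)
makes current the controlled variable. Per 10 ms step the simulator
computes

1. feedforward target current $i^*_k = \min(F^*_k / k_f,\; i_{\max})$;
2. current error $e_k = i^*_k - \hat i_{k-1}$ against the previous
   measurement (the loop has one sample of measurement delay);
3. PID drive $u_k = i^*_k + K_p e_k + K_i \sum_j e_j \Delta t +
   K_d (e_k - e_{k-1})/\Delta t$, clipped to $[0, i_{\max}]$
   (backward-Euler integral, first-difference derivative, no derivative
   filter; the integral is clamped at the current limit as anti-windup);
4. a first-order electrical lag
   $i_k = u_k + (i_{k-1} - u_k)\, e^{-\Delta t/\tau_e}$, discretised
   exactly so any $\tau_e$ is stable at the 100 Hz rate;
5. a quasi-static load divider
   $i^{\text{load}}_k = \alpha\, i_k$ with
   $\alpha = 1 / (1 + K/K_{\text{ref}} + C/C_{\text{ref}})$
   for skin stiffness $K$ and damping $C$
   ($K_{\text{ref}} = 2000$ N/m, $C_{\text{ref}} = 50$ N·s/m, the
   actuator's effective drive stiffness scale);
6. measurement $\hat i_k = i^{\text{load}}_k + \varepsilon_k$,
   $\varepsilon_k \sim \mathcal N(0, \sigma^2)$.

The block diagram the device publishes does not pin down the plant, so
the model was chosen as the simplest one reproducing the qualitative
behaviours that matter for evaluation: unloaded ($K = C = 0$,
$\alpha = 1$) the loop tracks the pulse; loaded, the delivered peak is
attenuated — monotonically in stiffness — exactly as seen on real skin,
while the integral term claws back part of the loss over the pulse; and
because the attenuation is a time-invariant gain and onset detection is
relative to each trace's own maximum, commanded lags survive the plant
unchanged. The attenuation is therefore reproduced qualitatively
(strict inequality), not quantitatively: neither the motor constants nor
the measured skin stiffness are published, so the defaults
($k_f = 1$ N/A, $\tau_e = 1$ ms, $i_{\max} = 4$ A, $R = 2.1\,\Omega$)
are placeholders that no analysis result depends on beyond those
invariants. The tab mass is validated but does not enter the
quasi-static force balance.

Whether the physical controller injected the feedforward current
directly or only through the PID path is not determined by the block
diagram; the simulator exposes `feedforward` (default `TRUE`, as drawn,
with the target current entering the comparison node).

**PID gains.** Mirroring the device's procedure, gains were tuned once
in unloaded, noiseless simulation and frozen: $K_p = 0.4$, $K_i = 2$,
$K_d = 0.005$ give a peak tracking error of 0.8 % on the 2 N pulse
(requirement: within 5 %). Only these stored defaults encode the tuning;
no gain is hard-coded in logic.

**Sensing noise.** The device does not characterise its current sensor,
so $\sigma$ is a generator calibration: $\sigma = 0.03$ A was chosen
once so that the per-trial onset-lag jitter has a standard deviation of
about 1.5 ms under the default configuration, and then frozen. This is a
modelling choice, not a measured property of any hardware.

## Lag verification

The analysis arm follows the published recipe exactly: traces are
upsampled to 1000 Hz by linear interpolation, smoothed, and each
channel's onset is the first sample *strictly* exceeding 10 % of that
trace's own maximum (earliest-sample tie-break). The per-trial lag is
$t_{\text{onset}}(H) - t_{\text{onset}}(V)$ in ms, so positive lags mean
"vertical first", matching the commanded-lag sign convention. Lags are
averaged within condition (mean ± SE over the 15 trials) and commanded
vs delivered condition means are compared with Pearson's $r$
(two-sided $p$ from the $t$ transform) plus the least-squares line for
the parity plot.

Two details are underdetermined by the recipe and fixed here:

* *Smoothing*: "linear interpolation and smoothing" becomes a zero-phase
  moving average, 11 samples (11 ms) at 1000 Hz with reflected
  boundaries — it suppresses sensing noise while moving the 6 Hz pulse's
  10 % onset by less than 1 ms (verified in the tests). The window is a
  parameter of `upsample_trace()`.
* *Correlation basis*: the published $r$ could be over 14 condition
  means or 210 trials; both are implemented
  (`analyze_lags(per_trial =)`) and the condition-mean variant — the one
  matching the published scatter plot of averaged dots — is the default.

## TOJ analysis

Responses are binary ("vertical first" = 1). Per participant and lag the
package computes the response proportion, then fits the two-parameter
logistic

$$P(\text{vertical first} \mid t) = \frac{1}{1 + e^{-(t-\mu)/s}}.$$

No lapse or guess parameters are fitted by default: with 15 trials per
lag they are practically unidentifiable, though the synthetic responder
can generate lapses for robustness experiments. The published analysis
fits "averaged probabilities", i.e. least squares on proportions; that
mode is available (`fit_mode = "proportions-ls"`), but the default is
maximum likelihood on the raw Bernoulli responses, which is statistically
preferable and asymptotically equivalent here. Both modes must — and do —
pass the same recovery tests.

Optimisation is deterministic: L-BFGS-B from $\mu_0$ = the lag whose
proportion is nearest 0.5 by linear interpolation and $s_0$ = lag
range / 8, with $s \in [1, 500]$ ms and a $10^{-8}$ relative tolerance
on the objective. Complete separation (perfectly ordered responses)
cannot be silently absorbed: the fit is returned with a warning, the
`separation` flag set and $s$ pinned at its lower bound. The PSE is
$\mu$; the JND is half the 25–75 % lag span, which for this logistic is
$s \ln 3$ analytically. `jnd_from_curve()` recomputes it by numeric
inversion of the fitted curve and must agree to $10^{-6}$ relative
tolerance — an internal consistency check, also exposed for
non-logistic extensions.

Group inference is a one-sample t-test of the per-participant PSEs
against 0 ms with $df = n - 1$. The tail is always an explicit argument
— a negative cross-over tested one-tailed is a directional hypothesis,
and the package refuses to default to the favourable direction. The
degenerate all-zero case returns $t = 0$, $p = 0.5$ with a flag instead
of `NaN`. `t_test_from_summary()` performs the same arithmetic from a
printed mean, SE and $n$, for reproducing published group statistics
when raw data are unavailable. A single planned test is run, so no
multiple-testing correction applies.

## Synthetic data: what it emulates, and what it does not

The generative responder is the analysis model run forwards:
$y \sim \text{Bernoulli}\bigl(\lambda/2 + (1-\lambda)\,
P(t)\bigr)$ with lapse $\lambda = 0$ by default. Its canonical
parameters are the published group values for this task, PSE
$-18.37$ ms and JND $25.15$ ms; cohorts draw per-participant
$(\mu, \text{JND})$ from normals centred there. The default
between-participant spreads, $\text{sd}_\mu = 12.5$ ms and
$\text{sd}_{\text{JND}} = 3.9$ ms, are $\sqrt{3}$ times the published
group standard errors, so a simulated 3-participant cohort exhibits a
comparable group SE — a calibration of the generator, not a published
measurement.

Because generator and analysis share the same family, recovery
experiments are well-posed: over 200 replicate datasets (14 lags × 15
reps) the median absolute recovery error of both PSE and JND stays
within 5 ms, and 200 three-participant cohorts recover the generating
group medians to within a few percent. What passing these tests shows is
that the *pipeline* is unbiased and precise under its own model; it does
not show that human observers follow a logistic, respond without lapses
or sequential effects, or that real motors match the plant model. The
published human results themselves (3 participants) are reproduced only
where arithmetic from printed summaries permits — e.g. $t = -18.37/7.21
= -2.548$, $df = 2$, one-tailed $p = 0.063$ — never by fitting to
unavailable raw data.

## Problem sizes and determinism

The standard experiment sizes are used throughout: 210-trial recording
sets for the device arm and 200 replicate datasets/cohorts for recovery
— large enough that the Monte-Carlo error on a median is a fraction of a
millisecond, small enough to run interactively. Every random step
(schedule permutation, sensing noise, responder draws, cohort draws)
flows from an explicit integer seed through a scoped RNG, so any result
in this package is bit-reproducible from `(config, seed)`; per-trial
noise streams are derived as `seed + trial_id`.

## Known limitations

* The plant is a gain-plus-lag abstraction: no back-EMF dynamics,
  mechanical resonance, drive-voltage saturation or wire slack. It is
  adequate for lag/peak evaluation, not for motor engineering.
* Only two channels are implemented; the architecture (per-channel
  motor parameters, shared load and loop) does not preclude more.
* Onset quantisation at the 1000 Hz analysis rate floors the achievable
  lag resolution at 1 ms.
* The psychometric model ignores reaction times, learning and fatigue;
  responses are exchangeable given the lag.
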