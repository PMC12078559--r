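---
title: "Models and methods behind photoswim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photoswim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoswim)
```

photoswim studies the motility of DNA condensates whose sticky ends carry
azobenzene photoswitches: visible light (trans isomer) stabilizes sticky-end
hybridization, UV light (cis) destabilizes it. Localized UV/Vis switching
inside such a condensate alternately discharges a dissolved DNA microflow
and pulls it back, and when the irradiated region covers only part of the
condensate, the condensate swims — away from the irradiated region at low
switching frequency ("push"), toward it at intermediate frequency ("pull").
The package implements the quantitative machinery for this system: a
two-state swimming model, MSD-based mobility analysis, displacement
kinematics, a temperature-to-flow-mode classifier, and synthetic ground
truth for validating all of it.

## The two-state swimming model

The condensate is reduced to two mass reservoirs: a Liquid domain of mass
$m_L(t)$ and a Dissociated domain of mass $m_D(t)$. Photoswitching events
are instantaneous; half-cycles ("UV-to-Vis" and "Vis-to-UV" intervals) last
$T$ time units each, so the switching frequency is $f = 1/2T$ (one full
UV+Vis cycle per $2T$; how many switches one counts per cycle is a pure
convention, and this one is configurable by constructing schedules
directly). Within each interval a lap clock $t'$ runs from 0 and resets at
the next switch.

During a UV-to-Vis interval a fraction $A(t')$ of the liquid mass per unit
time is discharged; a fraction $\lambda(t')$ of that discharge disengages
from the cyclic reaction by free diffusion, the remainder arrives in the
dissociated reservoir:

$$\dot m_L = -A(t')\,m_L, \qquad \dot m_D = (1 - \lambda(t'))\,A(t')\,m_L.$$

During a Vis-to-UV interval the reverse transfer runs with constant ratios
$B$ and $\kappa$:

$$\dot m_D = -B\,m_D, \qquad \dot m_L = (1-\kappa)\,B\,m_D.$$

Both growing ratios are diffusion-limited and saturate on a characteristic
diffusion time $\tau^*$; the package uses the saturating form

$$A(t') = A_{\max}\left(1 - e^{-(t'/\tau^*)^2}\right)$$

(and the same shape for $\lambda$, scaled by $\lambda_{\max}$). The
quadratic onset encodes the diffusion-limited build-up of the discharged
flow and the bound keeps a fractional rate below its maximum. The exact
functional form is not uniquely determined by the phenomenology, only its
qualitative features are; the form lives behind the one-argument functions
`disassembly_ratio()` / `disengagement_ratio()` so an alternative can be
swapped in.

Because $\lambda(t')$ grows with lap time while $\kappa$ is constant, short
intervals (high $f$) lose disproportionally little mass per cycle — this is
what makes the condensate lifetime increase with switching frequency.

### Momentum bookkeeping

The 1D liquid velocity $u(t)$ (positive pointing away from the irradiated
region) evolves by a momentum-exchange term and a viscous dissipation term,
$\dot u = \dot u^M + \dot u^T$, with $\dot u^T = -\gamma u$ in both
intervals. The exchange terms are built from momentum conservation:

* **UV-to-Vis (recoil).** Discharged mass is shed toward the irradiated
  region at relative speed $v_{\mathrm{eject}}$, so the liquid recoils:
  $\dot u^M = A(t')\,v_{\mathrm{eject}}$. The dissociated domain absorbs
  the ejected momentum — its bulk velocity $u_D$ (an explicit bookkeeping
  variable) is updated by mass-weighted mixing of the incoming ejecta
  moving at $u - v_{\mathrm{eject}}$ — and loses it slowly by diffusive
  randomization, $\dot u_D = -\beta u_D$.
* **Vis-to-UV (return).** Returning mass mixes into the liquid carrying
  the reversing-flow bias $-v_{\mathrm{reverse}}$ *plus* whatever negative
  momentum the dissociated domain conserved from the previous UV interval:
  $\dot u^M = (1-\kappa)\,B\,(m_D/m_L)\,\big((u_D - v_{\mathrm{reverse}}) - u\big)$,
  with $m_L$ floored at $10^{-12}$ to keep the ratio finite when the
  condensate is nearly consumed.

At low $f$ the long UV interval saturates $A$ and the recoil dominates
(push); by the time the flow returns, $\beta$ has randomized most of its
momentum. In tight intervals the recoil never leaves its weak quadratic
onset while the ejected momentum is still coherent when it returns, so the
return transfer drags the condensate toward the irradiated region (pull).
Setting `exchange_enabled = FALSE` ablates the Vis-to-UV exchange term
only; the recoil is then the sole propulsion source and the net
displacement is non-negative at every frequency — the model's way of
showing that the conserved momentum exchange is what makes the migration
direction frequency-dependent.

### Integration and numerical choices

Integration is forward (explicit) Euler with step $\Delta t$ (`dt`).
Validation enforces $A_{\max}\Delta t < 1$ and $B\Delta t < 1$ so masses
stay non-negative, and the interval length must be an integer multiple of
`dt` so switches land exactly on the Euler grid. Mass updates move each
transferred amount between exactly two ledger entries, so
$m_L + m_D + m_{\mathrm{lost}}$ is conserved to accumulated floating-point
error (tested at $10^{-9}$ relative). The model contains no randomness:
identical inputs give bit-identical series.

The lifetime of a run is defined as the first time $m_L$ falls below 10%
of its initial value (`Inf` if never); the threshold is a reporting choice,
not a model parameter.

### Default calibration

The shipped profile (`inst/extdata/defaults.yaml`) fixes the reference
conditions $m_L(0) = 100$, $m_D(0) = 0$, $\Delta t = 0.01$ and
$\tau^* = 800\,\Delta t$, and a default three-frequency sweep
$f \in \{0.0125, 0.125, 0.625\}$ (interval lengths $T = 40, 4, 0.8$,
i.e. $T \gg \tau^*$, $T \approx \tau^*/2$ and $T \ll \tau^*$) over a
horizon of 300 time units. The remaining constants
($A_{\max} = 0.3$, $\lambda_{\max} = 0.7$, $B = 0.3$, $\kappa = 0.05$,
$v_{\mathrm{eject}} = 0.5$, $v_{\mathrm{reverse}} = 2$, $\gamma = 0.2$,
$\beta = 0.02$) were calibrated once, by a coarse grid search over
physically ordered candidates (large diffusive loss under UV,
$\lambda_{\max} \gg \kappa$; comparable transfer rates $A_{\max} \approx B$),
to the qualitative regime pattern of the reference run, and then frozen:
push displacement and predominantly positive velocity at low $f$, a larger
pull displacement with lower peak speeds at intermediate $f$, minimal
displacement at high $f$, lifetime nondecreasing in $f$, and no negative
displacement anywhere once the exchange is ablated. All model units are
dimensionless.

## MSD analysis and the signed diffusion coefficient

`compute_msd_fft()` computes the time-averaged MSD of a uniformly sampled
2D track over all start points for every lag, using the standard
decomposition of the MSD into a running sum of squared norms and a
positional autocorrelation, the latter via FFT (Wiener–Khinchin). It is
exactly the naive $O(N^2)$ estimator `compute_msd_naive()` — the two are
cross-checked to $10^{-9}$ relative on randomized tracks — just
$O(N \log N)$. Non-uniformly sampled tracks are directed to the naive
path.

`fit_diffusion()` applies the truncation/fit-window protocol: keep the
first 20% of the positive lags, fit an unweighted least-squares line to the
largest 20% of the retained lags, and read $D' = \mathrm{slope}/4$ (2D:
slope $= 2dD$ with $d = 2$). The two stages are deliberately sequential
(truncate, then window within the truncated range) and both fractions are
exposed as arguments. Lags averaged over fewer than two displacement pairs
are dropped; a negative fitted slope — possible for a short track whose
late-lag MSD happens to bend down — is clipped to $D' = 0$ with a warning
rather than propagating a negative diffusivity. Note the protocol fits a
narrow window at fairly large lags, where single-track time-averaged MSDs
are intrinsically noisy; per-track $D'$ scatters widely and only ensemble
averages are quantitatively meaningful.

Flow direction is assigned per track from the net radial displacement with
respect to the irradiated-region centre (ensemble centroid at $t = 0$ when
not supplied): inward / outward, with an unclassified band below a 0.5 µm
noise floor; a manual override is accepted where an experiment was judged
qualitatively. The signed coefficient is then $D^* = -D'$ for inward flow
and $+D'$ otherwise, and `select_top()` keeps up to $k = 20$ tracks with
the largest $D'$ (ties broken by track id for stability). Whether "steepest
MSD curves" and "largest $D'$" select identical subsets is not guaranteed;
both criteria are available (`select_top()` on estimates vs. sorting curves
by late-lag value).

## Swimming kinematics and the threshold frequency

`displacement_series()` turns interface positions recorded at successive
switching moments into per-switch displacement vectors $\Delta r_i$, their
cumulative sum, the net displacement $L(t) = |\sum_i \Delta r_i|$ and its
maximum $L_{\max}$; `max_net_displacement()` tabulates $L_{\max}$ against
switching frequency.

`cycle_estimate()` implements the characteristic-cycle-time estimate: a
condensate of size $a$ whose UV-discharged flow spreads with effective
diffusion coefficient $D_S$ and whose Vis-reversed flow returns with $D_R$
traverses the distance $a$ in $a^2/4D$ each way (from
$\langle r^2(\tau)\rangle \sim 2dD\tau$, $d = 2$), giving

$$\tau_c = \frac{a^2}{4D_S} + \frac{a^2}{4D_R}, \qquad f_c = 1/\tau_c.$$

For the reference values $a = 20$ µm, $D_S = 20$, $D_R = 10$ µm²/s this is
$\tau_c = 15$ s and $f_c \approx 0.07$ s⁻¹. The coefficients are used in
µm²/s: that is the only unit under which $a^2/4D$ is a time, even though
mobilities are sometimes quoted in µm/s. Below $f_c$ the swimming is
dissipation-dominant (push), above it exchange-dominant (pull); the
boundary $f = f_c$ is assigned to the pull regime, an arbitrary tie-break
that `swim_regime()` flags explicitly. `print()` shows $f_c$ both rounded
to two decimals and at full precision.

## The temperature–flow-mode classifier

Each motif variant is described by four temperatures: gel→liquid transition
and dissolving temperatures, separately for the trans (Vis) and cis (UV)
isomer states, with the ladder gel < liquid < dissociated laid out as
half-open bands $[T_{GL}, T_D)$ compared at 0.1 °C resolution (a sharp
$T_{GL}$ is a simplification — rheologically the gel/liquid boundary may be
a crossover). The flow mode generated by UV/Vis switching is a pure
function of the two phase states:

| Vis (trans) state | UV (cis) state | mode |
|---|---|---|
| gel | dissociated | spread |
| gel | liquid | collapse |
| liquid | dissociated | spread-and-collect |
| anything else | | none |

The distinction between "fast" dissolution (spread) and the cyclic
out-and-back flow (spread-and-collect) is carried entirely by the initial
Vis-state (gel vs. liquid), matching the initial configurations under which
the two behaviours are observed.

The shipped fixtures for Y_2x1x5, Y_3x5 and Y_1x7 anchor the dissolving
temperatures that are known (50 °C and 65 °C under trans for Y_2x1x5 and
Y_3x5; ~3 °C under cis for Y_2x1x5) and back-solve the never-reported
$T_{GL}$ values from the observed mode ranges (spread below 40 °C for
Y_2x1x5, 45–60 °C for Y_3x5, above 60 °C for Y_1x7; collapse 35–50 °C only
for Y_1x7; spread-and-collect 40–45 °C for Y_2x1x5 and 55–60 °C for
Y_3x5). They are therefore derived fixtures, labelled synthetic, not
measurements. One observed overlap cannot be reproduced by any pure
function of the phase states: Y_3x5 shows spread over 45–60 °C and
spread-and-collect over 55–60 °C, which differ only in the initial state.
The fixtures place $T_{GL,\mathrm{trans}}$(Y_3x5) at 55 °C so the
classifier calls spread over 45–54 °C and spread-and-collect over
55–60 °C — every observed (variant, range, mode) row appears, with the
overlap band assigned to the liquid-initial behaviour. Enthalpy magnitudes
are passthrough annotation only; no thermodynamic estimation from melting
data is attempted.

## Synthetic ground truth

The generators produce exactly the statistical structures the analyses
assume, with the truth recorded: Brownian tracks with increments of
variance $2D\,\Delta t$ per axis; ballistic tracks with exact quadratic
MSD; radial spread/collapse ensembles (annulus start radii 20–50 µm,
radial drift ± diffusion, per-track direction labels) around a known
centre; and stepwise interface walks with persistent heading, log-normal
step lengths and an exponential step-length decay after a plateau onset
(push defaults: mean step 3 µm over few long intervals; pull defaults:
mean step 1 µm over more, shorter intervals). Localization error is
isotropic Gaussian noise, default 0.05 µm, the standard tracking-error
model; frame interval defaults to 0.2 s to match typical recordings. All
generators are deterministic under a fixed seed and restore the global RNG
state.

What the generators deliberately do not emulate: detection and linking
failures (dropped or swapped tracks), anisotropic or state-dependent
localization error, hydrodynamic coupling between particles, condensate
shape change, and drift of the field of view. Passing the validation suite
therefore shows the estimators are correct for their generating models,
not that real tracking data are free of those artefacts.

## Problem sizes and limitations

The validation suite runs the model at 30 000 Euler steps per run (horizon
300 at $\Delta t = 0.01$), the FFT/naive cross-check on 200 tracks of up
to 2048 samples, and the Brownian recovery benchmark on 50 tracks of 5000
steps — sizes chosen so the whole suite completes in well under a minute
while leaving the stochastic checks statistically meaningful.

Known limitations: the swimming model is 1D and spatially unresolved (no
concentration fields, no condensate shape, no 3D rolling); the exact
functional forms of $A(t')$, $\lambda(t')$ and the momentum-exchange terms
are phenomenological stand-ins constrained by qualitative behaviour, and
the momentum constants are a calibration, not measurements; the model is
not fitted to experimental movies; and the flow-mode classifier is a sharp
rule on derived fixtures.
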