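---
title: "Models and methods behind phaseloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phaseloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phaseloop)
```

phaseloop is an in-silico workbench for closed-loop optogenetic control of
the phase of gamma oscillations. It couples four pieces: a phenomenological
model of channelrhodopsin-2 (ChR2) photocurrents, a conductance-based
spiking-network simulator of one or two partially transduced populations, a
phase-analysis layer (phase-response curves, inter-areal locking), and an
online prediction pipeline that times a light pulse to a future target phase.
A surrogate generator of oscillations with autoregressive cycle-to-cycle
period fluctuations makes the analysis layers testable in seconds without
network simulation. This vignette explains the models, the parameter choices
and the numerical decisions in one place.

## The ChR2 photoconductance model

The light-evoked conductance is modelled as a product of one activating and
one (biphasically) inactivating factor,

$$F(t) = A_{act}\left(1 - e^{-(t - t_{ON} - d)/\tau_{act}}\right)
  \left(A_{persist} + A^{(1)}_{inact} e^{-(t-t_{ON}-d)/\tau^{(1)}_{inact}}
   + A^{(2)}_{inact} e^{-(t-t_{ON}-d)/\tau^{(2)}_{inact}}\right),$$

valid while the light is on; after light-off the conductance relaxes to zero
with a single time constant $\tau_{off} = 10$ ms. The two inactivation time
constants (9.06 and 59.6 ms) are global; latency $d$, activation time
constant $\tau_{act}$ and the three amplitudes depend on the relative light
intensity $W \in (0,1]$ through empirical laws (`chr2_kinetics()`), with
$A_{persist} = 1 - A^{(1)}_{inact} - A^{(2)}_{inact}$ enforced so the
inactivation factor stays positive. The laws make activation faster but the
fast-inactivating fraction larger at high intensity, which produces the
model's signature behaviour: the **peak** photocurrent of a short pulse is
maximised at an interior intensity, about 18% of the maximal deliverable
power (`chr2_optimal_intensity()`), not at full power. Intensities are
relative throughout; no absolute irradiance calibration is attempted.

The latency law $d = d_A + d_B W + d_C / W$ diverges as $W \to 0$, which is
the model's way of saying "no light, no response": intensities at or below
zero are rejected, and a negative computed latency is clipped at zero.

**Multi-segment stimuli.** Ramps are piecewise-constant segments (default
1 ms resolution). Activation state is continuous across contiguous segment
boundaries; the inactivation envelope restarts fresh when a segment begins
from darkness. Consequently cumulative desensitisation across well-separated
pulses is *not* modelled — the waveform is exact for the isolated short
pulses and the slow ramps used everywhere in the package, which is the
model's domain of validity.

**The coupling prefactor.** Two conventions are supported. The tabulated
prefactor (7 nS) together with a peak-normalised-order $F$ and a ~64 mV
driving force yields a peak current of ~0.3 nA, which is inconsistent with
the stated calibration that an optimal 3 ms pulse evokes a 2 nA peak in a
model neuron at rest. The default therefore re-derives the prefactor from
that calibration rule (`chr2_gain()`, about 43 nS); the tabulated value is
selectable with `chr2_params(g_mode = "printed")`.

**Fitting.** `chr2_fit()` reproduces the original two-stage calibration:
stage A fits all voltage-clamp traces jointly by bounded
Levenberg–Marquardt (minpack.lm) with the two inactivation time constants
shared across intensities; stage B fits the intensity laws to the
per-intensity estimates (at least four intensities spanning a decade). The
slow-inactivation decay rate can be held fixed to aid convergence, as in the
original calibration. Below roughly 3% intensity $\tau_{act}$ approaches
$\tau^{(1)}_{inact}$ and the product form becomes non-identifiable; recovery
tests therefore avoid that corner.

## The spiking network

Each area is a random network of Wang–Buzsáki (WB) single-compartment
neurons, 4 excitatory per 1 inhibitory (4000 + 1000 at full scale), with
instantaneous sodium activation, delayed bi-exponential synapses
(peak-normalised kernels; E: $\tau_{rise}/\tau_{decay}$ = 1/3 ms, I: 1/4 ms;
local delay 1.5 ms, long-range 1.0 ms), independent per-neuron Poisson
background drive (3 kHz through 0.5 nS excitatory events), and — on a
fraction $P_{ChR2}$ of both cell classes — the ChR2 conductance driven by a
shared per-area light waveform. Only excitatory neurons project between
areas. Strong delayed inhibition makes each area oscillate in the gamma
band through an interneuron-generated (ING) mechanism; the "LFP" is defined
as the mean membrane potential over all neurons of an area.

**Units.** Synaptic and noise peak conductances are interpreted in
nanosiemens. The literal microsiemens reading (selectable with
`conductance_units = "uS"`) would make a single inhibitory synapse 1800
times the leak conductance, which is not a usable operating point; the
nanosiemens reading preserves the printed ratios ($g_I/g_E = 36$,
$g_{noise} = g_E$) and produces gamma-band collective oscillations.

**Scaling.** Desk-scale work uses 400 E + 100 I per area
(`reference_config()`, `scale_factor = 0.1`) with recurrent peak
conductances scaled up by the inverse factor, preserving in-degree ×
conductance per synapse class; the per-neuron background drive is not
scaled. Mean synaptic drive is thus size-invariant, but fluctuations are
not: the scaled network has a lower synchronisation index, larger
collective phase diffusion, and coarser unitary synaptic events. Several
protocol-level consequences are discussed under *Limitations*.

**Integration.** Gating variables use exponential Euler at a fixed
dt = 0.05 ms. The membrane is advanced by exponential Euler on the
conductance form $dV/dt = -(g_{tot}/C)(V - V_{eff})$ rather than a forward
step: during synchronous inhibitory volleys the compensated scaled network
transiently reaches $dt \cdot g_{tot}/C > 2$, where a forward update is
unconditionally unstable, while the exponential update is stable for any
conductance. Halving dt changes population rates by under 2% (tested).
Spikes are upward crossings of −20 mV.

**Reproducibility and frozen noise.** Topology, transduction mask, initial
conditions and every per-neuron Poisson stream are functions of four named
seeds; the noise streams are per-neuron counter-seeded xorshift generators
whose state is part of the serialisable simulator state. A run restarted
from a checkpoint continues bit-identically, so a perturbed run differs
from its unperturbed twin *only* through the light-evoked current. The
phase-response and locking protocols exploit this: the unperturbed run is
simulated once with checkpoints at the onset times, and each pulse
experiment restarts from its checkpoint.

## Phase analysis

Phases live on the cyclic unit interval. The Hilbert phase
(`hilbert_phase()`) is the analytic-signal angle of the demeaned LFP after
a zero-phase Butterworth band-pass centred on the spectral peak (±20 Hz),
shifted so that **phase 0 sits at upward zero crossings** of the
band-passed signal. The origin is a convention (it is nowhere standardised
for this analysis); all waveform and PRC statements in the package use it
consistently, and the separation between the waveform maximum and minimum
(≈ 0.3 cycles) is reported as the convention-free check. The linear phase
(`linear_phase()`) grows uniformly between zero crossings; on network LFPs
it tracks the Hilbert phase up to a mild static non-linearity which the
online pipeline deliberately ignores.

An induced phase shift (`measure_phase_shift()`) is the circular mean of
the instantaneous Hilbert-phase difference between the perturbed and
unperturbed twins over post-onset cycles 11–60 (10 transient cycles
discarded, 50 averaged). The PRC (`estimate_prc()`) bins these shifts by
the onset phase — always attributed on the *unperturbed* twin, the only
unambiguous choice under frozen noise — into 30 bins; pulses default to
3 ms at the optimal 18% intensity.

## Inter-areal locking

Two symmetrically coupled areas phase-lock with two mirror modes
($\Delta\phi_{locked}$ and $1-\Delta\phi_{locked}$; either area leading).
`locking_modes()` finds them by circular kernel-density peaks rather than a
fixed threshold. The pulse protocol (`locking_experiments()`) verifies a
locked pre-state (20 cycles before onset) with the transduced area leading,
then classifies short-term *shifting* (>10% relative change of the phase
difference over post-pulse cycles 1–5; an absolute-threshold mode is also
provided) and long-term *switching* (50-cycle mean within ±0.05 of the
opposite mode, after 10 discarded cycles), each against matched
spontaneous baselines from the unperturbed run. The default pre-lock
criterion (circular std < 0.05) describes full-scale locking; at desk
scale the inter-areal phase difference has circular std ≈ 0.24 even within
locked epochs, so the desk-scale protocol documented here uses
`lock_tol = 0.35` — with the strict threshold every desk-scale experiment
would be discarded.

## The online prediction pipeline

The closed loop (`run_closed_loop()`) follows the stages: **testing**
(windowed FFT of demeaned 256 ms chunks; the monitoring stage starts when
the gamma-band peak exceeds 5× the median broadband power in both areas at
a common frequency — the threshold is configurable since only its role, not
its value, is prescribed), **monitoring** (≈ 20 cycles filtered online with
the two-pole resonator $y_t = x_t + \alpha_1 y_{t-1} + \alpha_2 y_{t-2}$,
$\alpha_2 = -0.99$), **prediction** (zero crossings with sub-sample
interpolation, mean period $\bar T$, the lag-1 coefficient $a$, and the
onset forecast), and **stimulation** from a simulator checkpoint, so the
realised onset phase can be measured on the unperturbed continuation.

Numerical decisions in this pipeline:

* **Resonator coefficient.** The standard resonator
  $\alpha_1 = 2\sqrt{-\alpha_2}\cos(2\pi f_{peak}/f_s)$ is the default; the
  alternative tabulated form $4\alpha_2\cos(2\pi(1-f_{peak}/f_s))/(1-\alpha_2)$
  has the same magnitude at $\alpha_2=-0.99$ ($4\cdot0.99/1.99 = 2\sqrt{0.99}$)
  but the opposite sign convention, which mirrors the resonance to
  $f_s - f_{peak}$ under this recursion; both are implemented and tested.
* **Filter lag.** A causal resonator delays its output by a known,
  frequency-dependent amount (≈ 0.2 cycles at resonance;
  `resonator_lag()`). Crossing times are compensated by the lag evaluated
  at an entrainment-free frequency estimate (raw-window spectral peak),
  because the buffer's own mean period is pulled toward the filter centre
  whenever the testing-stage estimate is off-centre. The monitoring window
  is also preceded by a 500 ms filter pre-roll so that the resonator's
  ring-in transient (time constant ≈ 200 samples) has died away.
* **Forecast form.** The s-step AR(1) forecast adds
  $\frac{a^{s+1}-a}{a-1}$ times the last period's *deviation*
  $(T_k - \bar T)$ to the linear forecast $t_k + s\bar T$; this is the
  statistically standard form and the default. A variant that multiplies
  the full period $T_k$ instead is selectable (`variant = "literal"`), and
  both are tested. At $a = 0$ the correction vanishes and the two schemes
  coincide exactly. On Gaussian AR(1) periods the one-step AR(1)/linear
  error ratio is $\sqrt{1-a^2}$, which the package verifies by Monte Carlo;
  below $a \approx 0.3$ the improvement is marginal, matching the
  rule of thumb used to decide when linear extrapolation suffices.
* The prediction window defaults to $s = 3$ cycles (≈ 50 ms of a 40–70 Hz
  rhythm), the time budget a hardware implementation of these linear
  computations would need.

## The surrogate generator

`surrogate_spec()` defines oscillations whose period lengths follow
$T_i = \bar T + a(T_{i-1} - \bar T) + \epsilon_i$ with Gaussian residuals
(stationary initialisation; periods clipped at $0.1\bar T$, which at the
default $\sigma_\epsilon/\bar T \approx 0.06$ is never reached). Each cycle
renders a waveform template warped to its period — a sinusoid, or a skewed
template whose maximum is displaced late in the cycle to mimic the
asymmetric rise/fall of inhibition-dominated gamma — plus optional white
measurement noise; the ground-truth phase grows linearly within each cycle.
Defaults ($\bar T = 18$ ms i.e. ~55 Hz, $a = 0.3$, $\sigma_\epsilon = 1$ ms)
correspond to a weakly autocorrelated gamma rhythm of the kind the network
produces in its synchronous regime. The generator emulates band-limited
rhythms with AR(1) period structure and nothing else: no amplitude
dynamics, no 1/f background, no nonstationary frequency wander. Passing the
round-trip and forecast-theory tests on surrogates therefore validates the
estimators, not the network's predictability.

## Problem sizes used by the tests and the acceptance script

All network-based checks run the documented desk scale: 400 E + 100 I per
area, 12 s reference recordings (> 480 cycles), 100–150 frozen-noise onset
pairs for PRCs, 40 pulse experiments for the two-area protocol, ≈ 2100
cycles for spontaneous-switching statistics, and 12 closed-loop trials.
These are the package's desk-scale study conditions; the full-size network
(5000 neurons per area, 1500 onsets) is available behind
`scale_factor = 1`.

## Limitations

* **Finite-size effects dominate several desk-scale statistics.** At
  1/10 scale the collective phase diffuses quickly: after a pulse the
  frozen-noise twins decorrelate within tens of cycles, so induced shifts
  averaged over post-onset cycles 11–60 carry per-onset noise of ~0.25–0.3
  cycles, and the 30-bin PRC argmax is unstable at 100–150 onsets (the
  positive lobe around onset phases 0.12–0.18 is nevertheless visible in
  the bin means). The two-area motif locks only loosely (circular std
  ≈ 0.24) with near-in-phase modes and spontaneous mode flips every few
  tens of periods, and closed-loop realised phases scatter with circular
  std ≈ 0.3–0.4, consistent with prediction error growing as synchrony
  falls. All of these are finite-size effects that recede as
  `scale_factor` approaches 1.
* **Firing rates.** Under the tabulated parameters both cell classes
  receive statistically identical input, so their mean rates are equal
  (~8–10 Hz in the synchronous regime) rather than the low, class-distinct
  rates sometimes quoted for such networks; no parameter in the printed set
  breaks the E/I symmetry of the drive.
* The LFP is the population-mean membrane potential; there is no
  extracellular forward model. Connectivity is homogeneous random, without
  spatial structure or plasticity. The ChR2 model is phenomenological (no
  photocycle states) and omits desensitisation accumulation across
  well-separated pulses.
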