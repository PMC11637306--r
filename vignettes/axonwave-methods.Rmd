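---
title: "Models and methods behind axonwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind axonwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(axonwave)
```

axonwave studies a deceptively simple question about thin unmyelinated
axons such as hippocampal mossy fibers: their diameter varies severalfold
along a single fiber (a ~0.2–0.3 µm shaft strung with 0.5–4 µm en passant
boutons and occasional giant boutons), so does the action potential (AP)
change shape from bouton to bouton, and with it the calcium influx and
transmitter release each bouton produces? The package provides the full
computational machinery to pose that question in silico: a compartmental
cable model with uniform ("homogeneous") or size-compensated channel
densities, AP waveform metrics, calcium-influx and release mapping, the
local-capacitance measurement used to quantify "size" electrically, a
forward model of the recording instrument with a fitting-based correction,
and a voltage-imaging processing chain — all exercised on seeded synthetic
data so that every stage is testable without external recordings.

## The membrane and cable model

Each compartment obeys

$$C \frac{dV}{dt} = -I_\mathrm{ion}(V) + I_\mathrm{axial} + I_\mathrm{inj},$$

with Hodgkin–Huxley-type currents
$I_\mathrm{Na} = \bar g_\mathrm{Na} m^3 h\,(V - E_\mathrm{Na})$,
$I_\mathrm{K} = \bar g_\mathrm{K} n^4 (V - E_\mathrm{K})$, an optional
compensatory potassium current with its own $n$-type gate, an ohmic leak,
and a calcium current carried by a P/Q : N : R channel mixture
(permeability ratio 6.5 : 2.5 : 1) whose open-channel flux follows the
Goldman–Hodgkin–Katz constant-field equation. Defaults follow standard
values for this preparation: $C_m = 1\,\mu F/cm^2$, $R_a = 150\,\Omega$ cm,
$R_m = 50\,k\Omega\,cm^2$, $E_\mathrm{leak} = -80$ mV, $E_\mathrm{K} = -90$
mV, $E_\mathrm{Na} = +70$ mV, $\bar g_\mathrm{Na} = 290$ and
$\bar g_\mathrm{K} = 17$ mS/cm². Calcium gate kinetics carry a
$Q_{10} = 2.5$ factor from a 24 °C reference to the 35 °C working
temperature; intracellular calcium is held constant (the model computes
influx, not accumulation).

**Kinetic calibration.** The Na/K rate equations are the canonical
squid-axon forms with a configurable uniform voltage shift (default
+5 mV) and per-gate kinetic scale factors. The defaults
(`rate_scale_na = 6`, `rate_scale_h = 12`, `rate_scale_k = 8`) were chosen
once so that the model axon fires a brief 35 °C-like AP: half-width about
0.35 ms, amplitude about 130 mV, full repolarization within roughly 1 ms.
One aspiration we examined and rejected as unreachable: with the fixed
densities above, the AP peak cannot sit near +20 mV in this rate family —
at the peak the open sodium conductance (~100–150 mS/cm²) dwarfs
$\bar g_\mathrm{K} = 17$ mS/cm², pinning the peak near a weighted reversal
of +55 to +69 mV for any potassium kinetics we tried (including
high-threshold, Kv3-like shifts, which instead produced depolarization
block). The separate inactivation scale `rate_scale_h` exists precisely
because peak height is controlled by how much Na inactivation overlaps the
upstroke; all of these parameters are free in the instrument-fitting
pathway.

**Integration.** Voltages advance by an implicit backward-Euler step
(optionally the trapezoid rule via `theta = 0.5`) with the branched axial
coupling solved exactly at each step by a tree-ordered elimination, and
gate variables advance by the exact exponential (Rush–Larsen) update at
frozen voltage. The default step is 4 µs (250 kHz). The GHK calcium
current is treated explicitly within a step; it is small relative to the
Na/K currents, and the convergence checks below bound the total error.
Waveform convergence under halving of `dt` and of the compartment length
is asserted after aligning waveforms at their peaks: refining the
discretization slightly shifts conduction delay, and comparing unaligned
traces would measure that irrelevant shift rather than waveform error.
Compartments are at most 1 µm long by default (metrics are taken "at every
micrometer"), with frustum (truncated-cone, slant-corrected) membrane
areas and axial resistances $4 R_a L / (\pi d^2)$ split into half
resistances at the compartment faces.

## Geometry and the synthetic axon

Morphologies are SWC-style node tables; `make_axon()` draws a
mossy-fiber-like varicose axon: a 400 µm shaft of 0.3 µm diameter with 15
boutons at jittered regular spacing, log-normal diameters (median 1 µm,
clipped to 0.5–4 µm), and one giant 3.5 µm bouton. Varicosities are
Gaussian bumps whose width scales with a quarter of the bouton diameter,
so a bouton rises and falls over about its own diameter — the steep necks
seen in reconstructions. All diameters stay within the 0.1–5 µm range
typical of unmyelinated axons. The generator is a pure function of its
seed.

What the generator does *not* emulate: branching and collaterals,
filopodial appendages, continuous caliber drift of the parent axon,
reconstruction noise, and the somatodendritic compartment (stimulation is
an axonal current step near one end). Passing tests on this geometry
therefore demonstrates the machinery on an idealized varicose cable, not
on the full anatomical complexity of a real fiber.

## Size dependence of the AP, and what this model actually shows

With homogeneous densities, a uniform cable admits a traveling-wave
solution whose temporal waveform is independent of diameter (the diameter
drops out of the co-moving cable equation), so any size dependence of the
AP must come from impedance mismatch at caliber changes and from
boundaries. On the synthetic varicose axon the model robustly reproduces
"smaller is slower" in the kinetic metrics: AP half-width, width at
−20 mV, and maximal rise and decay rates all correlate negatively with
local capacitance (r ≈ −0.1 to −0.25 per compartment). The
repolarization-phase *area* behaves differently: large boutons fire with a
slightly higher peak (a nearly isopotential blob expresses the full
membrane AP, whereas the shaft wave is attenuated by its axial load), and
inside the area integral this amplitude excess offsets the narrower width,
leaving the area-versus-capacitance slope near zero or weakly positive in
every variant we examined. We report both the slope and the width
correlations in `run_experiment("size_dependence")` so users see the two
faces of the effect; treat area-based size correlations from this model
family as fragile.

The nonlinear downstream cascade is unaffected by that subtlety: calcium
influx density (charge per membrane area over a 5 ms window from AP
onset) varies along the axon with AP shape, and relative release is the
2.5-power of influx, mean-normalized. Release is computed from influx
*density* rather than per-bouton totals: totals scale with bouton area, and
raising them to the 2.5 power would make the giant bouton dominate any
spread statistic by orders of magnitude; density isolates the AP-driven
variability the analysis is about. The headline spread statistic is the
relative range (max − min)/mean across boutons, with the population CV
reported alongside; on the default axon the release relative range comes
out close to 40%.

**Compensation and in-silico dendrotoxin.** The compensatory (Kv1-like)
potassium density can be distributed as scale/(local capacitance), i.e.
inversely with size, with the scale chosen by a golden-section search
minimizing the across-bouton SD of the repolarization area — the
experiment's explicit objective, standing in for the per-recording fits a
laboratory would do. Zeroing that current afterwards is the in-silico
analogue of blocking Kv1 channels with dendrotoxin; because small
compartments carry more of the compensatory density, its removal widens
their APs more. On these synthetic conditions the optimal one-parameter
profile reduces the across-bouton SD by roughly three-fold (and the
release spread modestly); the residual variability is dominated by
neighborhood mismatch effects that no purely size-indexed density profile
can null.

## The local-capacitance probe

The probe mirrors the experimental pipeline: a −20 mV voltage-clamp step
(−70 to −90 mV), subtraction of the averaged cell-attached trace, and
multi-exponential fitting of the capacitive transient. Fits use separable
least squares (amplitudes and offset are linear given trial time
constants) refined by Nelder–Mead on log time constants, with five
log-spaced starts plus nested starts seeded from the best lower-order fit
— which guarantees the SSE ordering sse(tri) ≤ sse(bi) ≤ sse(mono). Time
constants are constrained to what the window can resolve (no faster than a
quarter of the window start, no slower than 20× its end). Model selection
defaults to the two-compartment (biexponential) reading: mono wins only
within 10% of the bi SSE, tri only when it improves bi by more than 10%.

Two measurement choices deserve explanation:

* **Fit window.** The default window is 0.2–5 ms after the transient peak
  — a window of roughly five milliseconds *length* starting just after the
  peak, not a window *starting* at 3 ms. With realistic access resistances
  (100–300 MΩ) and structure capacitances of a few pF, the fast component
  decays with τ ≈ 0.2–1 ms and is numerically extinct by 3 ms; a window
  that starts at 3 ms can neither distinguish mono- from biexponential
  behavior nor recover the capacitance at realistic noise. Both window
  bounds are arguments.
* **Access-divider correction.** The fast-component charge
  $A_f \tau_f$ underestimates the local capacitance by the squared
  voltage-divider ratio $R_p/(R_s + R_p)$ (the local membrane only sees
  the fraction of the step surviving the access resistance). The divider
  is estimated from the fit itself — the ratio of the back-extrapolated
  slow-plus-offset current to the total current at the step onset — and
  divided out. The correction is exact for an ideal two-compartment
  circuit and is on by default (`series_correction`).

The synthetic two-compartment circuit behind these tests (access 150 MΩ,
local 2 pF with a 25 GΩ local membrane resistance — i.e. 50 kΩ cm² at the
implied area — and 1.5 pF of nearby axon behind 1.5 GΩ) is solved in
closed form by eigen-decomposition, so recovery tests compare against
exact component values.

## The instrument model and AP correction

The pipette is a five-segment RC ladder (40 MΩ, 6 pF by default) with its
resistance concentrated toward the tip (60/20/10/6/4%), an access
resistance into the cell, a 12 GΩ seal leak at the tip, capacitance
neutralization that cancels a fraction (default 0.9) of the pipette
capacitance, and bridge balance that subtracts the injected-current IR
drop from the recorded voltage. Recording through this instrument
attenuates the AP and broadens its half-width while changing the area
comparatively little — the robustness property that motivates area-based
AP comparisons; the property is asserted across a 3×3 grid of pipette
R/C settings. Bridge balance is exact only in the steady state, so a brief
artifact follows each stimulus edge; analyses of instrument recordings
start 0.4 ms after the stimulus onset, and protocols use near-rheobase
stimuli so the AP fires well clear of the artifact.

Passive parameters (specific capacitance, axial resistivity, access
resistance) are fitted to subthreshold responses with the membrane
resistance fixed at 50 kΩ cm². Conductance fitting then varies
$\bar g_\mathrm{Na}$, $\bar g_\mathrm{K}$, the voltage shift and the
kinetic scales within bounds (densities up to 5× default, shifts ±20 mV,
scales 0.2–5×) by Nelder–Mead with simplex restarts — the budget is split
into three rounds, each restarted at the previous optimum, because a
single Nelder–Mead run stalls in the narrow valleys of this objective —
from four initializations, and the parameters of all optimizations are
averaged. Rerunning the averaged model without the instrument predicts
the native AP. The outside-out patch protocol steps a single-compartment
patch from −110 mV to 0 mV for 0.4 ms (peak inward current = I_Na) and to
+70 mV (late-window mean outward current = I_K), with P/4-style leak
subtraction scaled to each step.

## The imaging pipeline

Synthetic fluorescence follows
$F(t) = F_0\, b(t)\, (1 + s\,(V - V_\mathrm{rest})/100\,\mathrm{mV})$ with
fractional sensitivity $s = 8\%$ per 100 mV, a double-exponential bleach
$b(t)$ (τ = 50 and 500 ms), and mixed shot plus read noise, rendered at
10 kHz on a 64×46 pixel grid (0.79 µm/px). Bleaching is corrected per
pixel after clustering pixels into eight mean-intensity bins and fitting a
double exponential to each bin's event-masked time course (AP windows are
excluded so the signal does not leak into the bleach estimate; bins that
fail fall back to a mono-exponential and are flagged). Activity maps are
(peak-window mean − baseline)/baseline per pixel with a ±0.2 ms window;
axon pixels average into ≤5 µm path segments.

Temporal super-resolution uses the shift-and-mean scheme: each trial's
frames are aligned by its high-rate electrical reference peak, the pooled
samples are sorted, and consecutive groups of eight samples are averaged
in both time and value. The effective output rate is reported (about
25 kHz for twenty pooled 10 kHz trials); block averaging uses a fixed
sample count, so the rate varies with trial count rather than being a
constant. Per-trial jitter is modelled as a uniform frame-phase offset
within one frame period plus 4 µs Gaussian detection error on the
electrical reference. Optional two-step zero-phase Butterworth filtering
(10 then 100 kHz for oversampled signals; 2 then 20 kHz for
stimulation-evoked APs) skips any cutoff at or above the Nyquist rate with
a message. The VSD AP area integrates the peak-normalized waveform over a
0.6 ms window starting 0.05 (or 0.1) ms after the peak; normalization
precedes the metric because VSD amplitudes depend on background intensity
and are not comparable across recordings.

## Problem sizes and determinism

The packaged experiments run on a 400 µm axon (≈800 compartments) for
8–28 ms of simulated time at 250 kHz, VSD datasets of 20 trials × 14–30 ms,
and 100-replicate probe recoveries; each experiment completes in seconds
to a few minutes on one core. Every generator and experiment is a pure
function of its seed: rerunning with the same configuration reproduces
every number exactly (optimizer-based stages inherit determinism from
seeded initializations).

## Known limitations

* The kinetic family is calibrated squid-form HH; the real fiber's
  channel complement (Kv3/BK backbone, Kv1 compensation, Na subtype
  gating) is reduced to three currents with configurable parameters.
* Intracellular calcium dynamics, buffering, and microdomain geometry are
  out of scope; influx is the endpoint.
* The area-versus-capacitance slope under homogeneous conductances is
  near zero in this model family (see above); conclusions that hinge on
  its sign should use the width- and rate-based metrics instead.
* The instrument model is a lumped ladder, not a calibrated replica of a
  specific amplifier; its parameters are explicit and configurable.
* Release mapping is relative (mean-normalized) with a fixed cooperative
  power; no vesicle-pool or short-term plasticity dynamics.
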