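---
title: "A reduced mouse sinoatrial cell model for seizure-induced sinus arrhythmias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced mouse sinoatrial cell model for seizure-induced sinus arrhythmias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Epileptic seizures derange autonomic outflow to the heart, and the sinus
arrhythmias that follow — ictal tachycardia that degenerates into
bradycardia or asystole, postictal low-frequency oscillations of the heart
rate, postictal arrest — are candidate triggers of sudden unexpected death
in epilepsy (SUDEP).  The classical explanation is purely neurogenic:
every firing-pattern change is attributed to a time-varying autonomic
command.  `sancpace` implements the complementary cardiogenic hypothesis
as a simulation pipeline: hold the autonomic inputs *fixed* within each
seizure phase (an "autonomic clamp") and ask which arrhythmic phenotypes
the sinoatrial nodal cell (SANC) produces on its own, through its
intracellular ion dynamics.  A second layer asks how circadian time and
vigilance state (sleep versus wakefulness, including force-decoupled
combinations) reshape that susceptibility.

## The cell model

The core is a reduced Hodgkin–Huxley model of a single mouse SANC with
eleven state variables: membrane potential $V$; activation/inactivation
gates $d_L, f_L$ and a Ca-dependent inactivation gate $f_{Ca}$ for the
L-type Ca current; $d_T, f_T$ for the T-type current; $y$ for the
hyperpolarization-activated "funny" current; $n$ for the delayed-rectifier
K current; intracellular Na and Ca concentrations; and a slow adrenergic
effector state described below.  Membrane currents are the two Ca
currents, $I_{HCN}$, $I_K$, the muscarinic K current $I_{KACh}$, the Na/K
pump $I_{NaK}$, the Na–Ca exchanger $I_{NCX}$, and a background Na
current; optional background-Ca and plasma-membrane Ca-pump terms exist in
the parameter set but are off by default.  All equations live, readably,
in `R/currents.R`; the integrator runs a line-for-line C translation
(`src/sanc_model.c`) that a property test keeps in lock-step with the R
reference.

Units are seconds, mV, mM, pA, pF, pL and nS throughout; firing rates are
reported in beats per minute (BPM).

The design of the fast subsystem follows the Morris–Lecar recipe: a
steeply activating inward Ca current against a delayed-rectifier K
current, with the diastolic depolarization carried by the funny current,
the T-type window and background Na.  Three slower processes sculpt the
arrhythmias:

* **Intracellular Na** (seconds to tens of seconds).  Each action
  potential imports Na (background Na, the Na fraction of $I_{HCN}$, and
  three Na ions per NCX cycle); the Na/K pump exports it with a steep
  (Hill coefficient 3) dependence on Na.  Sustained tachycardia therefore
  loads Na and raises a hyperpolarizing pump current.
* **Cytosolic Ca** (seconds).  Ca entry through the L- and T-type
  currents, removal by NCX; Ca overload closes the L-type current through
  $f_{Ca}$, whose steady state is $K_m/(K_m + \mathrm{Ca}_i)$.
* **The adrenergic effector** `pka` (time constant 15 s).  Sympathetic
  upregulation of the Ca-channel conductances follows this first-order
  state rather than the instantaneous drive, reflecting the slow
  phosphorylation arm of β-adrenergic signalling, while the cAMP action
  on HCN (an activation-curve shift, saturating at ±14 mV) is
  instantaneous.  This timescale split is what lets a clamped sympathetic
  surge produce tachycardia *first* and Ca/Na-overload depression *later*
  — the within-phase dynamics that are the package's point — without any
  time-varying input.

At baseline drive the model fires tonically at ≈391 BPM with an
inter-spike-interval coefficient of variation below 0.005, and
intracellular Na settles near 8.2 mM.

## Autonomic and environmental modulation

Sympathetic (`sna`) and parasympathetic (`pna`) drive are dimensionless
multipliers of their preictal baselines (baseline = 1 by convention).
Their conductance transfers are piecewise:

* Ca channels: $1 + a(p-1) + a_2(p-1)^2$ in the effector state $p$,
  floored at the basal fraction 1 below baseline.  The quadratic term is
  what carries mixed tachycardia–bradycardia into frank asystole at high
  surge strength; the floor means sympathetic *withdrawal* acts only
  through HCN, so the denervated cell keeps its basal Ca-channel activity.
* HCN: linear conductance gain in `sna` plus the saturating activation
  shift.
* $I_{KACh}$: unit gain below baseline (no transmitter, no current), a
  shallow linear gain above it, and a quadratic sensitisation that engages
  beyond twice-baseline vagal tone — deep-postictal territory — so that
  ictal-range vagal variation modulates rate without dominating the
  ictal outcome, while postictal parasympathetic dominance can silence
  the cell.

Body temperature enters through Q10 factors: 2.3 on gating rates, 1.3 on
conductances, and a deliberately steeper 3.5 on the Ca-channel
conductances, making the warm (waking) phase of the temperature rhythm
arrhythmogenic for the ictal phase.  The local circadian rhythmicity
(LCR) multiplier scales $I_{HCN}$ proportionally.

Circadian context uses cosine waveforms: parasympathetic tone ±50%
peaking at ZT6 (daytime sleep for a nocturnal mouse), body temperature
±1 °C and LCR ±20% peaking at ZT18.  Sympathetic tone carries no
circadian variation.  The five canonical states are natural ZT18 (awake),
ZT12 (transition), ZT6 (sleep), plus forced sleep at ZT18 and forced
wakefulness at ZT6, built by phase-shifting only the parasympathetic
waveform by 12 h.

## The seizure protocol

An event lasts 4 minutes: 60 s preictal (from a converged steady state),
a step at onset to the clamped ictal levels $S\times(1+S_i)$ and
$P\times(1+P_i)$ held for 60 s, a 45 s linear ramp to the postictal
levels $S\times(1+S_p)$ and $P\times(1+P_p)$, then 75 s at those levels.
Defaults assume ictal sympathetic dominance ($S_i > P_i$), postictal
parasympathetic dominance ($P_p > P_i$) and minimal postictal sympathetic
tone ($S_p = -100\%$).  Each protocol segment is integrated separately
with lsoda (rtol $10^{-6}$, atol $10^{-8}$), so the onset discontinuity
is a breakpoint rather than a solver surprise; output is resampled at
1 kHz regardless of internal steps.  Tightening both tolerances tenfold
moves no spike in a 240-s oscillatory event by more than 1 ms.

## Classification and burst analysis

Spikes are upward crossings of −20 mV followed by a local maximum (with
parabolic sub-sample timing and a 20 ms refractory).  A sampling window —
the last 15 s of the clamp for the ictal phase; 15 s starting 30 s after
the ramp for the postictal phase, letting transient post-ramp arrest
clear — is labelled **N** (no firing) when its count rate falls below
30 BPM, **I** (irregular) when the ISI coefficient of variation exceeds
0.15, any ISI exceeds three times the median (burst gaps), or amplitude
alternans (>5% alternating beat-to-beat difference over ≥4 beats) is
present, and **R** (rhythmic) otherwise.  Crossing ictal and postictal
labels yields the nine-region taxonomy
($\mathrm{id} = 3\,\mathrm{rank}(\mathrm{ictal}) +
\mathrm{rank}(\mathrm{postictal}) + 1$, with R, I, N ranked 0, 1, 2).
All thresholds are exposed as arguments.

## What the simulations show

With the default parameter set (identical for every analysis):

* Sweeping $S_i$ at fixed $P_i$ walks the ictal window through
  R → I → N; sweeping $P_p$ walks the postictal window through the same
  ladder; the nine (ictal, postictal) combinations are all realised by
  the 3 × 3 trace sample in `analysis/02_seizure_traces.R`.
* In the oscillatory (I–I) event, ictal bursts run near 0.77 Hz on an
  elevated Na plateau (≈10.7 mM) while postictal bursts run near 0.20 Hz
  at depleted Na (≈7.8 mM) — the same frequency and Na ordering as the
  phenomenon under study, though the absolute numbers belong to this
  reduced model, not to the original full-scale one.
* Steady firing is fastest awake (≈447 BPM, ZT18) and slowest asleep
  (≈359 BPM, ZT6).
* On 8 × 8 maps, wakefulness (natural or forced) expands the ictal
  no-firing fraction relative to natural sleep, while sleep (natural or
  forced) expands the postictal no-firing fraction relative to natural
  wakefulness — the postictal risk follows the vigilance state, not clock
  time.
* Applying the circadian factors one at a time shows the
  parasympathetic channel dominating the postictal outcome at both ZT18
  and ZT6, with body temperature the main ictal factor.

## The synthetic-trace generator

`trace_spec()`/`generate_trace()` emulate membrane-potential recordings
with prescribed structure — regular pacing at 300–600 BPM, clustered
bursting at 0.1–0.4 Hz, quiescence, amplitude alternans, jittered pacing
— by placing stereotyped action-potential waveforms (raised-cosine
upstroke, exponential repolarization, 40 ms wide, peak +20 mV) on a
−60 mV baseline.  The generator exists to validate the detector and
classifier against designed ground truth, so its noise model is plain
(multiplicative ISI jitter, optional white Gaussian baseline noise,
deterministic under a seed) and it makes no attempt to emulate
intracellular ion series or coloured electrode noise; a perfect score on
it demonstrates that the analysis stages recover *designed* structure,
not that they are robust to every artefact of experimental recordings.
The classifier recovers the designed labels perfectly noise-free and at
≥95% under 2% ISI jitter (200-case suite).

## Numerical and design choices

* **Problem sizes.**  Maps in the tests and the acceptance script run at
  8 × 8; the full 40 × 40 protocol resolution is a single argument away
  and uses the identical code path.  Steady-state searches allow up to
  90 s of simulated time; events are the standard 240 s.
* **Equation provenance.**  The behavioural contract (murine-range tonic
  pacing; surge-induced tachycardia, Na loading, bursting, asystole;
  vagal slowing and arrest; circadian orderings) defines the model; the
  equations are a fresh reduced formulation tuned to that contract, not a
  transcription of any published parameter set.  Where the published
  protocol left constants unstated (circadian amplitudes, classification
  thresholds, autonomic transfer shapes), the values here are declared
  package defaults, config-exposed, and chosen once.
* **Supralinear transfers and the effector state.**  A purely linear,
  instantaneous conductance scaling cannot produce both an acute
  sympathetic tachycardia and a delayed collapse into asystole within one
  clamped phase; the quadratic escalation riding on the slow `pka` state
  is the minimal mechanism that does.  Similarly, the piecewise vagal
  transfer separates the rate-modulating (ictal) from the silencing
  (postictal) regime of $I_{KACh}$.
* **Monotonicity.**  Over the 0.8–1.2 drive neighbourhood the steady
  rate rises with sympathetic and falls with parasympathetic drive to
  within a 1% tolerance band; the sub-percent ripples come from the slow
  Na equilibrium shifting under the pump.
* **Determinism.**  The model is deterministic; random seeds matter only
  to the synthetic-trace generator.  Map sweeps are serial with stable
  ordering, so reruns are bitwise identical.
* **Degenerate inputs.**  Non-finite states are rejected, never clamped;
  per-point solver failures leave missing map cells rather than aborting
  a sweep; steady-state non-convergence raises a condition carrying the
  last state.

## Limitations

The model is a single isolated cell: no SAN tissue heterogeneity, no
atrial loading, no respiratory coupling, no autonomic feedback, and no
chronic epileptic remodelling.  Quantities tied to the precise channel
complement of a full-scale SANC model — absolute burst frequencies,
absolute Na concentrations, the exact placement of region borders —
should be read as qualitative counterparts, not predictions.  The
vigilance states are phenomenological (a 12-h phase shift of one
waveform), deliberately so.
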