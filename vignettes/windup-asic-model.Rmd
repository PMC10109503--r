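---
title: "A WDR neuron model of windup with proton-gated ASIC1a channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A WDR neuron model of windup with proton-gated ASIC1a channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windupasic)
```

# The system being modelled

Deep dorsal-horn wide-dynamic-range (WDR) projection neurons receive
convergent input from A-delta and C fibers.  Under 1 Hz repetitive
electrical stimulation of their receptive field, the number of action
potentials they fire in the C-fiber and post-discharge latency windows
grows over the train — *windup*, a short-term spinal pain facilitation.
ASIC1a-containing acid-sensing ion channels at the C-fiber postsynapse are
gated by the transient acidification of the synaptic cleft during
transmission.  The package simulates this loop end to end: each stimulus
drives both fibers, each C-synapse activation injects a 1-ms proton pulse
into its cleft, the cleft pH gates the local ASIC population, and the ASIC
current (10% of it booked as calcium) feeds back on the neuron's
excitability through depolarization, the calcium-activated nonspecific
cation current (CaAN) and the calcium-activated potassium current (KCa).

# Model components

## ASIC1a gating

Gating is Hodgkin–Huxley-like with activation $m$ and inactivation $h$
driven by pH only:

$$m_\infty(\mathrm{pH}) = \frac{1}{1 + 10^{\,n_m(\mathrm{pH} - \mathrm{pH}_{0.5m})}},
\qquad
h_\infty(\mathrm{pH}) = \frac{\alpha}{1 + 10^{\,-n_h(\mathrm{pH} - \mathrm{pH}_{0.5h})}}$$

| variant | $n_m$ | $\mathrm{pH}_{0.5m}$ | $n_h$ | $\mathrm{pH}_{0.5h}$ | $\alpha$ |
|---|---|---|---|---|---|
| homomeric native | 1.5 | 6.46 | 4.6 | 7.3 | 1.3 |
| heteromeric native | 1.94 | 6.03 | 3.82 | 6.74 | 1 |

Activation is treated as strictly instantaneous ($m := m_\infty$ every
step): its time constant is orders of magnitude below the windup timescale,
and no pH-dependence for it is part of the native-current fits.
Inactivation relaxes exponentially with a pH-dependent time constant in
seconds — a biased Gaussian for the homomeric fit,
$\tau_h = 49.196\,e^{-34.632(\mathrm{pH}-7.144)^2} + 0.95\,\mathrm{pH} - 3.77$,
read with an affine (not reciprocal) linear term, and a symmetrized
exponential for the heteromeric fit,
$\tau_h = 42.862\,e^{-5.375\,|\mathrm{pH}-6.6|} + 1.645$ s.  Two
alternative homomeric forms (affine and piecewise-affine in pH) are
available for robustness scans.  $\tau_h$ is validated over pH 4–9; outside
that range evaluation errors by default, and a 1-ms floor guarantees
positivity if range checking is disabled.  The current law is
$I = g\,m\,h\,(V - E)$ with $E = +50$ mV; `mittx = TRUE` locks the open
fraction $mh$ at exactly 1 regardless of pH, emulating the sustained,
inactivation-free activation produced by the Texas coral snake toxin.
No resting pH shift is applied anywhere.

Note one structural consequence of the homomeric parameters: at pH 7.4 the
window product $m_\infty h_\infty \approx 0.036$ is small but nonzero, so
an ASIC population contributes a standing depolarizing trickle even in a
never-acidified cleft.  Setting the proton influx to zero therefore
removes all *dynamic* (acidification-driven) modulation but not this
constant term.

## Synaptic cleft acidification

The state variable is the total (free plus buffer-bound) proton
concentration

$$\frac{d}{dt}\Big[\,H\Big(1 + \frac{B_0}{H + K_d}\Big)\Big] = q(t) \;-\; \frac{H - H_0}{\tau}$$

with $B_0 = 22$ mM, $K_d = 10^{-6.3}$ M, $H_0 = 10^{-7.4}$ M, and a square
influx pulse $q = 0.3$ mM/ms of 1 ms duration at every presynaptic
activation (membrane crossing $-30$ mV; activations within 1 ms coalesce).
Concentrations are held in mM and time in ms internally; pH is
$-\log_{10}$ of the free concentration in molar.  The buffering factor at
rest is $\approx 4\times 10^4$, which converts the nominally stiff
$\tau = 0.1$ ms homeostatic term into an effective free-proton relaxation
of seconds: single pulses acidify by ~0.08 pH units and decay slowly, so
1 Hz trains accumulate acidification toward a quasi-steady pH ≈ 7.15 where
per-period influx equals per-period clearance.  Each of the 20 C synapses
owns its cleft (ASICs and the pulse trigger are defined per synapse); a
`shared_cleft` flag pools them into one compartment instead.  The influx
amplitude is capped at 2 mM/ms, the physiological bound for a 20-nm cleft.

## The host WDR neuron

The host neuron is a deliberate re-creation, not a reimplementation: the
windup literature's model structure (dendrite, soma, axon initial segment;
AMPA/NMDA on both fiber classes; GABA_A, NK1 and ASICs on C synapses;
L-type Ca, CaAN and KCa currents with intracellular calcium pools) with
canonical kinetics filling every slot the source material leaves open.
Specific capacitance is 2.4 uF/cm2, KCa densities are 2 mS/cm2 (soma) and
2.5 mS/cm2 (dendrite), and the printed receptor conductances are used
as-is.  Everything else — geometry, Traub–Miles Na/K kinetics, Boltzmann
L-type activation, Hill coefficients, calcium gains and extrusion time
constants, leak — is the package's calibrated reference set, chosen once
against four behavioral targets:

1. fewer than 10 C + post-discharge spikes at the first stimulation
   (the stimulus-intensity criterion);
2. a monotone windup curve reaching its maximum between stimuli 13 and 16;
3. windup abolished (last-stimulus count ≤ 1.2 × first) when the NK1
   conductance is zeroed;
4. the ASIC conductance series orderings described below.

The windup mechanism that emerges from the calibration is a slow ignition:
AMPA volleys fire a handful of spikes per stimulus from the start; NMDA
(Jahr–Stevens magnesium block) and L-type calcium charge the dendritic
calcium pool; the steep CaAN activation
($\mathrm{Ca}^6/(\mathrm{Ca}^6 + K_d^6)$, $K_d = 2.5$ uM) functions as a
switch that the slowly summating NK1 depolarization tips over the course
of the train, producing the late growth and the post-discharge.  The KCa
activation is broader ($n = 4$, $K_d = 5$ uM) and engages at the higher,
sustained calcium loads produced by strong ASIC activity — the brake that
implements the inhibitory arm of the bell shape.  Because the NK1
conductance is only 3 pS per synapse against 6 nS of AMPA, its leverage
comes entirely from temporal summation near this ignition threshold; its
decay time constant (not printed in the source material; metabotropic NK1
responses last tens of seconds) is set to 9 s, which makes the 1 Hz
summation factor ≈ 9.5 and the NK1 standing current a few tens of pA —
of the same order as a moderate (0.2 nS) ASIC population, consistent with
the reported similarity of the two currents.

Calcium is one lumped pool per compartment with first-order extrusion,
parameterised directly by an influx gain (uM per pA·ms — the shell volume
folded into one number) and an extrusion time constant (1.5 s dendrite,
1 s soma).  Calcium sources are the L-type current plus 10% of NMDA, NK1
and ASIC currents, inward portions only.

## Scenario variants

`scenario_config()` exposes the pharmacological axes: ASIC variant and
per-synapse conductance (0–15 nS), the calcium fraction (0 for the
calcium-free variant), MitTx mode, `kca_scale` (0 = apamin + iberiotoxin
block), `nk1_scale`, cleft parameters, and the seed that draws the
synaptic delays (A-delta uniform on [20, 60) ms, C uniform on
[120, 260) ms, so monosynaptic responses land in their latency windows and
every C delay exceeds every A-delta delay).

The reference behaviors, each asserted by the test suite:

* moderate homomeric conductances (0 → 0.2 nS) monotonically raise the
  windup AUC; 1.4 nS drops it below both the 0.2 nS run and control
  (bell shape with an interior maximum);
* removing the ASIC calcium fraction at 1.4 nS removes the inhibition and
  strongly potentiates; blocking KCa at 1.4 nS rescues windup;
* MitTx mode at 0.2 nS suppresses windup below control — the constitutive
  calcium load engages KCa before the train even starts;
* the heteromeric variant reproduces the same pattern over a higher
  conductance range (rise to 3 nS, decline at 15 nS);
* both alternative cleft parameter sets, (q = 1 mM/ms, tau = 0.01 ms) and
  (q = 0.05 mM/ms, tau = 1 ms), preserve these orderings despite very
  different pH time courses.

## Windup quantification

Spikes are classified by latency from the stimulation artifact into
half-open windows [0, 20), [20, 90), [90, 350), [350, 1000) ms (A-beta,
A-delta, C, post-discharge); the half-open convention is ours — it makes
the classification a partition.  The windup curve counts C plus
post-discharge spikes per stimulus.  The AUC is the trapezoidal area of
the counts above the first-stimulus baseline with negative excess clipped
to zero (the area-above-baseline convention of the common analysis
software); a `clip = FALSE` flag gives the signed area.  Percent
inhibition between paired conditions is $100(1 - \mathrm{drug}/\mathrm{control})$,
computed from totals and from AUCs separately; zero control denominators
yield `NA` rather than an error.

## The surrogate-recording generator

`gen_recording()` emulates the *statistical shape* of in vivo WDR spike
tables, not their biophysics: expected C-window counts follow the
saturating growth law $\mu_i = N_1 + (N_{max}-N_1)(1 - e^{-(i-1)/\kappa})$
(defaults $N_1 = 4$, $N_{max} = 20$, $\kappa = 3$, which plateaus by
stimulus 13), post-discharge and A-delta spikes are added at configurable
rates, counts are Poisson (negative-binomial switch for over-dispersion),
and latencies are truncated log-normals inside each window.  Paired
cohorts scale the drug condition's expectations by $1 - f$ with fresh
noise.  What passing recovery tests show is therefore that the *pipeline*
is unbiased at realistic count levels (a programmed 50% inhibition is
recovered within ±3 percentage points at n = 15 neurons over 200
cohorts) — not that the generator captures serial correlation, electrode
artifacts, or neuron-to-neuron heterogeneity of real recordings, which it
does not attempt.

# Numerical choices

* Engine step `dt = 0.025` ms.  Voltages advance by exponential Euler in
  total-conductance form (synaptic and ASIC conductances folded in);
  gating variables use exact exponential updates with rates evaluated at
  the midpoint voltage, which removes most of the first-order splitting
  bias; ASIC inactivation uses the exact exponential update at the
  current cleft pH; the cleft ODE is sub-stepped explicitly at ≤ 0.005 ms.
* The axon initial segment's densities keep the fastest membrane time
  constant at or above the step, so spikes are resolved.  On halving the
  step the control windup count changes by about ±2 of ~260 (≈ 0.8%) with
  no systematic drift; individual near-threshold spikes flip because the
  plateau-ignition dynamics amplify any perturbation, so convergence is
  quantified at the 1% level rather than spike-for-spike.
* Runs are fully deterministic given configuration and seed (the seed
  enters only through the synaptic delay draw).
* Numerical divergence (|V| > 200 mV) aborts with the offending time.
* The free-from-total proton inversion uses the conjugate form of the
  quadratic formula to avoid cancellation at physiological pH, and is
  tested against a log-space bisection oracle at 1e-12 relative error.

Problem sizes are chosen for desk-scale reproducibility: 15-stimulation
protocols (16 s of model time, a few seconds of wall time each), a
100-stimulation run for the long-horizon pH validity criterion, and grid
searches at whatever resolution the question needs — the shipped tests use
coarse grids.

# The (q, tau) validity scan

The proton influx amplitude and the homeostatic time constant are the two
least-constrained cleft parameters.  `parameter_scan()` classifies each
(q, tau) cell by three criteria: cleft pH stays above a floor over a long
train (default pH ≥ 7.0 over 100 stimulations — the long horizon excludes
parameter sets that only look physiological because the simulation ends
early), windup AUC within ±25% of the reference run, and last-stimulus
count within ±30%.  The glyphs defining the original tolerances did not
survive into the source text, so these thresholds are interpretive
defaults, exposed as arguments.  The shipped default (q = 0.3 mM/ms,
tau = 0.1 ms) passes all three.

# Known limitations

* The host neuron is calibrated to behavioral targets, not fitted to
  voltage traces; all figure-level comparisons are qualitative (orderings
  and shapes), and absolute spike counts should not be over-interpreted.
* The KCa-block scenario at high ASIC conductance saturates into tonic
  maximal-rate firing — the ordering (blocking the brake rescues and
  overshoots windup) is the meaningful output, not the saturated counts.
* One presynaptic event per fiber per stimulus; afferent burst structure
  is not modelled.
* The in vivo inhibition percentages of ASIC-blocking toxins depend on the
  unknown in vivo ASIC conductance and are not fitting targets; the
  percent-inhibition machinery is validated on surrogate cohorts with
  programmed effects instead.
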