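---
title: "A spiking basal-ganglia network model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking basal-ganglia network model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bgnet)
```

## The scientific problem

In chronic low-dopamine states such as Parkinson's disease (PD) the basal
ganglia (BG) show two robust electrophysiological signatures: exaggerated
beta-band (12-30 Hz) oscillations and synchrony in the ongoing activity of
the subthalamic nucleus (STN), external globus pallidus (GPe) and the output
nuclei, and an altered *transient* response of the substantia nigra pars
reticulata (SNr) to brief cortical stimulation.  In a healthy animal a brief
cortical volley evokes a characteristic triphasic SNr pattern: early
excitation (EE, via the hyperdirect cortex-STN-SNr route), early inhibition
(EI, via the direct cortex-striatum-SNr route), late excitation (LE, via the
indirect route through striatum, GPe and STN), followed by a late inhibition
(LI).  Under dopamine depletion the EI phase can disappear, leaving a
biphasic excitation-inhibition pattern.

`bgnet` implements a reduced spiking network model of the BG that reproduces
both phenomena from first principles, together with the complete analysis
pipeline (PSTH zone segmentation, response signatures, beta-band metrics) and
the perturbation experiments (weight sweeps, restorations, lesions, dopamine
sweeps, phase-conditioned stimulation) that identify which connections shape
the transient response.  Everything is generated synthetically: the only
inputs are homogeneous Poisson background drives and a rate-modulated Poisson
stimulus.

## Model

### Populations and neurons

The network holds 6539 neurons in seven populations: striatal D1 and D2
spiny projection neurons (2000 each), striatal fast-spiking interneurons
(FSI, 80), STN (388), arkypallidal and prototypical GPe (GPe-TA 329, GPe-TI
988) and SNr (754).  Striatal neurons and the STN are leaky
integrate-and-fire (LIF) units,

$$C \dot V = -g_L (V - E_L) - I_{syn}, $$

spiking when $V \ge V_{th}$ with reset to $V_{reset}$ and a 2-ms refractory
period.  GPe and SNr neurons are adaptive exponential (AdEx) units with the
exponential spike-initiation term $g_L \Delta_T \exp[(V - V_T)/\Delta_T]$
and an adaptation current $w$ ($\tau_w \dot w = a(V - E_L) - w$, $w \to w +
b$ at each spike), which gives them tonic pacemaking and rebound firing on
release from hyperpolarization.  All per-population constants are exposed by
`neuron_params_table()`.  Two printed oddities of the parameter set are kept
deliberately: the STN excitatory reversal potential of $-10$ mV, and the
interchanged-looking excitatory/inhibitory synaptic time constants of the
two GPe populations.  The AdEx spike-cutoff potential is not printed in the
source tables; we use 0 mV (the dynamics above roughly $-30$ mV take well
under a millisecond, so the choice is immaterial at 0.1-ms resolution).

### Synapses

Synapses are conductance-based with an alpha-function transient
$g(t) = J\,(t/\tau)\,e^{1 - t/\tau}$ that peaks at exactly the weight $J$
(nS) at lag $\tau$ after the conduction delay.  A signed weight selects the
channel: negative weights drive the inhibitory conductance (reversal
$E_{in}$), positive the excitatory one ($E_{ex}$); the conductance amplitude
is $|J|$.  The 22 projections (in-degree, weight, delay) are listed by
`projection_table()`; connectivity is fixed in-degree: each target neuron
draws exactly $K$ distinct presynaptic partners uniformly at random, without
autapses or multapses.  Out-degrees are left binomial; no spatial structure
is imposed.

### Dopamine

A tonic dopamine level $\alpha_{dop} \in [0, 1]$ enters every modulated
quantity linearly through $\phi = \alpha_{dop} - 0.8$ (the healthy state is
mapped to 0.8, full depletion to 0): neuron excitability as $E_L \to E_L (1 +
\beta_{EL}\,\phi)$ (D1-SPN, FSI, GPe, SNr; D1-SPN additionally scales
$V_{th}$), and synaptic weights as $w \to w (1 + \beta\,\phi)$ with
per-projection sensitivities.  D2-SPN and STN excitability are not modulated
by default (a toggle exists for the D2 control experiment).  Three condition
presets are provided: `normal` ($\alpha_{dop} = 0.8$), `PD-biphasic`
($\alpha_{dop} = 0$ with the default sensitivities) and `PD-triphasic`
(identical except for three altered sensitivities - D2-SPN->GPe-TI,
D1-SPN->SNr, GPe-TI->STN - that recover a triphasic transient response in
the depleted state).  Delays are never modulated.

### Integration

The coupled system is integrated at $dt = 0.1$ ms: the linear alpha-synapse
states advance by their exact exponential update, the membrane (and
adaptation) equations by an explicit midpoint (RK2) step.  During the AdEx
spike upswing the raw RK2 midpoint voltage is unbounded; it is clamped at
the spike cutoff before entering the second stage so that the adaptation
update never sees the numerical blow-up (without this clamp the adaptation
increment - and hence network rates - depends visibly on $dt$).  Delays are
implemented as a per-edge ring buffer; every delay in the parameter tables
is an exact multiple of $dt$, and this is asserted.  Initial membrane
potentials are drawn uniformly between $E_L$ and threshold to desynchronize
the start; the stimulation-onset jitter (below) additionally discards the
startup transient.  Step-size robustness is covered by a test comparing
population rates at $dt = 0.1$ and $0.05$ ms; note that a *deterministic*
AdEx cell near its spiking bifurcation is bistable and is not a meaningful
step-size probe, so the test uses a noise-driven population, which is the
regime the network operates in.

## Synthetic inputs

### Background drive and its calibration

Every neuron receives an independent homogeneous Poisson excitatory train
with a per-population rate and a fixed nominal 3-nS weight (two free knobs
per population would be unidentifiable, so only rates are calibrated; the
unitary weight was fixed once at a value whose shot noise keeps the healthy
network in an asynchronous-irregular regime - a much smaller unitary weight
delivers the same mean conductance as a nearly deterministic drive and the
coupled pallido-subthalamic loops then lock into runaway beta synchrony).  For
striatum and STN this stands for cortical/thalamic input; for GPe and SNr it
stands for endogenous depolarizing drive.  `calibrate_background()` tunes
the rates until simulated baseline rates fall inside the published target
intervals (normal: D1/D2 in [0.01, 2] Hz, FSI in [10, 20], STN in [10, 13],
GPe-TA 11.8 +/- 1.1, GPe-TI 24.2 +/- 0.7, SNr in [20, 35]; the low-dopamine
state has its own targets, e.g. STN in [26, 29] and GPe-TI in [17, 20]).
Because the populations are strongly coupled - and the depleted network
oscillates - joint damped updates diverge; calibration is therefore a
per-population line search (geometric bracketing followed by bisection in
log-rate space) inside an outer loop that visits the populations
upstream-first (striatum and STN, then GPe, then SNr).  The shipped
per-condition rate files (`default_background()`) are the frozen outcome of
this procedure.

Two calibration outcomes deserve explicit mention.  First, the depleted
network's behaviour is extremely sensitive to where the D2 rate sits inside
its published [1, 2] Hz band: the striato-pallidal drive is the knob that
unleashes the beta oscillation, and moving D2 from 1 Hz to 2 Hz takes the
population Fano factor from ~15 to several hundred.  The shipped depleted
presets sit near the lower edge of the band, where the oscillation strength
matches the published oscillation index and Fano factor.  Second, at that
operating point the prototypical pallidum cannot simultaneously reach its
published depleted-state rate band of [17, 20] Hz: with the subthalamic rate
pinned at 26-29 Hz the printed subthalamo-pallidal weight alone drives
GPe-TI to ~26 Hz, and the D2 drive needed to force it lower is exactly the
drive that saturates the oscillation.  The calibration reports this residual
rather than distorting the oscillation level.

### Transient cortical stimulus

Cortical stimulation is modelled as a rate-modulated Poisson train delivered
to a configurable fraction (default 50%) of the D1, D2 and STN populations:
a rectangular excitatory pulse followed by a rectangular suppression of the
stimulated neurons' background to a sub-baseline level, mimicking the brief
excitation-then-inhibition cortical response.  The numeric pulse shape and
the cortex-to-target conduction delays are not published; they are free
parameters fitted *once*, in the healthy condition only, against three
anchor features of the SNr response (EE latency 7 ms, EE duration 4 ms, EI
latency 11 ms), and then frozen (`default_stimulus_profile()`).  The frozen
profile is a rectangular 3000 spikes/s x 4 ms pulse followed by suppression
of the stimulated neurons' background to 30% for 20 ms, with stimulus
weights of 0.9 / 1.5 / 2.2 nS onto D1, D2 and STN and conduction delays of
1.0 ms (cortex to striatum) and 2.0 ms (cortex to STN); in the healthy
network it yields EE at 7-8 ms lasting 4 ms, EI at 12 ms lasting 6 ms and
LE at 18 ms.  An optional lower plateau segment and a smooth raised-cosine
pulse shape are available for exploring alternative cortical waveforms.  All other
reported features, and every low-dopamine run, are out-of-sample with
respect to this fit.  The per-target stimulus weight is scaled by the
cortical dopamine sensitivities, so at $\alpha_{dop} = 0$ the cortico-STN
stimulus is 1.92x stronger and the cortico-D1 stimulus 6x weaker than in
the healthy state.  Stimulus onsets are drawn uniformly in [700, 900] ms per
trial; responses are recorded over 1200-ms trials.

### What the generator does and does not emulate

The synthetic inputs reproduce: independent Poisson drive per neuron,
identical across-trial rate profiles with per-trial realizations, onset
jitter, and dopamine-scaled stimulus weights.  They do not attempt realistic
cortical dynamics (inputs are inhomogeneous Poisson only), short-term
plasticity, NMDA-type synapses, spatially structured connectivity, phasic
dopamine, or single-neuron response heterogeneity - the model is homogeneous
within populations, so all neurons of a population share one response
profile.  Passing tests therefore demonstrate the network-level mechanism,
not a fit to any individual in vivo recording.

## Analysis pipeline

### PSTH and zone segmentation

Responses are summarized as PSTHs with 1-ms rectangular bins over 100 ms
before to 250 ms after each trial's own onset, averaged over trials and
neurons; the pre-stimulus 100 bins define the baseline mean and SD.  A bin
is significant when its one-tailed Z statistic exceeds 1.645 (p < 0.05);
a zone opens at the first of at least two consecutive significant bins of
one polarity and closes when two consecutive bins fall below significance
(the end time is the last significant bin).  Episodes are labelled in
temporal order with alternating polarity (EE, EI, LE, LI); consecutive
same-polarity excitations with no inhibitory episode between them are merged
and reported under EE (the convention for the biphasic depleted response);
a single inhibition following the final excitation is LI.  The search is
restricted to [0, 250) ms, episodes beyond the fourth are ignored with a
warning, and undetected zones are flagged rather than erroring.  Each
detected zone yields six features: latency, duration, absolute area (sum of
absolute deviations from baseline), mean and SD of bin heights, and peak
amplitude (reported as deviation from baseline where the experiment tables
require it).

### Signatures and distances

The 24-component response signature concatenates the six features over the
four zones in fixed order.  Distances between signatures are plain Euclidean
norms over the raw components (the mixed ms/Hz units are kept raw, matching
the printed formula; undetected zones contribute zeros and carry a marker -
two signatures are only compared when their markers agree, except in
restoration experiments where a zone may legitimately appear or vanish).
Subpopulation statistics re-extract the features from 100 random subsets of
50% (or 20%) of the SNr population.

### Steady-state metrics

Ongoing activity is simulated for 5 s per trial without stimulus.  The
population Fano factor is the variance/mean of 3-ms-binned population spike
counts (1 for an uncorrelated Poisson ensemble).  The oscillation index is
the fraction of spectral power of the mean-subtracted 3-ms-binned rate
(sampling frequency 333.3 Hz) inside 12-30 Hz, relative to the total up to
Nyquist; the spectrum estimator is a trial-averaged periodogram, with the DC
component removed by mean subtraction (the source is silent on whether DC
was included; mean subtraction is the adopted reading).  Phase
relationships band-pass the 1-ms population rates at 12-30 Hz (zero-phase
fourth-order Butterworth - only the band is published), take Hilbert phases,
and histogram the absolute phase differences folded into [0, pi] with 100
bins.

## Experiment protocols

Each protocol is a deterministic function of its arguments and a master
seed: transient runs per condition (including STN-only stimulation), the
stimulated-fraction sweep (10-100%), seven-point geometric weight sweeps
v/m ... m v for six connections (m is the low-dopamine scaling factor; for
D1-SPN->SNr the grid is the same but its low-dopamine end is the *small*
magnitude side), restoration of single projections (weights and delays reset
to healthy values, background recalibrated to healthy targets before
measuring, per the published restoration conditions), the lesion battery
(projections removed with *no* recalibration, measuring the raw
consequence), dopamine-level sweeps (0 to 1; background rates interpolate
linearly between the calibrated depleted and healthy drives), and
phase-conditioned stimulation (stimulus-free preview trials locate onsets at
a requested beta phase of the SNr rate; re-running the identical seed with
the stimulus reproduces the pre-onset trajectory exactly, so the stimulus
arrives at the requested phase).  Sweep-pooled diversity tables pool the
grid points one step around normal (healthy pool) or the three steps toward
the depleted extreme (low-dopamine pool).

## Problem sizes

Headline experiments in the source use 100 trials per condition and 100
5-s trials for steady-state metrics.  The package's default examples, test
suite and the bundled acceptance script run the same protocols at reduced
scale - typically 12-20 trials for transient features and 6-10 trials of
3-5 s for steady-state metrics, with the lesion battery at 3 x 3 s - which
keeps every zone latency/duration stable to the millisecond and the
oscillation metrics stable to well within their across-trial variability.
The vignette and README report numbers produced at these scales.

## Known limitations

* The exact cortical stimulus waveform and the background rates of the
  source model are unpublished; the calibration targets substitute for them,
  so absolute response amplitudes are reproduction goals rather than exact
  replications.
* In the depleted (biphasic) condition this implementation does not
  reproduce a *merged* 22-ms excitation: the 1.92x-strengthened cortico-STN
  volley recruits a prototypical-pallidum burst whose nigral inhibition cuts
  the excitation at ~11-16 ms, so a short early-inhibitory episode remains
  statistically detectable.  Longer, softer, plateaued and smooth pulse
  shapes, and rearranged conduction delays, either break the healthy-state
  anchors or leave the gap; the package reports the zones it actually
  detects.  Relatedly, the depleted late inhibition is split by the ongoing
  beta rhythm rather than forming one ~34-ms block, and the
  depleted-triphasic early-excitation amplitude saturates near 100 spikes/s
  (stronger volleys recruit proportionally stronger pallidal
  counter-inhibition).
* The healthy network retains a residual pallidal beta fluctuation
  (oscillation index ~0.25 for GPe-TI, similar to the depleted value,
  although its Fano factor is ~4x smaller): at its published operating
  point GPe-TI tolerates essentially no independent background drive, so
  its fluctuations remain locked to shared network input.
* The published oscillation index and Fano factor are quoted per condition
  without naming a population; this package reports them for GPe-TI, the
  central oscillator population, where the depleted values match the
  quoted numbers.
* The beta generator of this implementation is the subthalamo-pallidal
  loop: disconnecting STN<->GPe-TI collapses the depleted oscillation,
  whereas the published lesion battery reports that disconnection as
  ineffective (with the striato-pallidal projection as the essential
  pathway).  Removing D2-SPN->GPe-TI does normalize the synchrony here as
  well - the two implementations agree on that half of the dissociation.
  Similarly, the restoration experiment's distance ranking is dominated by
  the area components of this implementation's oversized late zones, so the
  closest-to-healthy restoration can come out as the pallido-pallidal
  collaterals rather than the striato-pallidal projection at small trial
  counts.
* The AdEx parameter set places GPe cells near a spiking bifurcation where
  a deterministic, noise-free cell is bistable; all shipped experiments
  operate in the noise-driven regime.
* No short-term plasticity, NMDA synapses, interneuron diversity beyond
  FSIs, or spatial connectivity; single-neuron response diversity is out of
  scope by construction.
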