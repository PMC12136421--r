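---
title: "Model and methods: interleaved single-spike and burst resonance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: interleaved single-spike and burst resonance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(burstres)
```

CA1 pyramidal neurons emit two kinds of output events: isolated single spikes
(SS) and bursts (BS), runs of spikes with interspike intervals under 14 ms.
`burstres` implements a conductance-based model of such a neuron together with
the complete analysis chain needed to study how the two event types respond to
oscillatory (theta and gamma) drive: spike detection and burst
classification, firing rate and ISI coefficient of variation, per-type
frequency tuning curves and resonance summaries, spike phase-locking
statistics, quiet-interval-conditioned event probabilities, and a
voltage-imaging event pipeline validated on synthetic fluorescence traces.

## The model

The membrane equation per compartment is

$$C\,\frac{dV}{dt} = -g_L (V - E_L) - \sum_j I_j - I_{ac} + I_{app} + \sqrt{2D}\,\xi(t),$$

with conductance-based currents $I_j = g_j m^M h^N (V - E_j)$ and white noise
$\xi$ applied to the somatic voltage only. The soma carries transient sodium
(NaT; $m_\infty^3 h$), persistent sodium (NaP; $p_\infty$), delayed-rectifier
potassium (KDR; $n^4$), muscarinic potassium (KM; $z$), A-type potassium
(KA; $a_\infty^3 b$), high-threshold calcium (HCa; $r^2$), and fast and slow
calcium-activated potassium currents (fKCa: $d_\infty([Ca]) \, c$;
sKCa: $q$ with $q_\infty = [Ca]^4/([Ca]^4 + a_q^4)$). Voltage gates follow
first-order kinetics $dx/dt = (x_\infty(V) - x)/\tau_x(V)$ with Boltzmann
steady states $x_\infty(V) = \{1+\exp[-(V-\theta_x)/\sigma_x]\}^{-1}$, and the
calcium pool obeys $d[Ca]/dt = -\nu I_{HCa} - [Ca]/\tau_{HCa}$
($\nu = 0.13$, $\tau_{HCa} = 13$ ms). In the two-compartment configuration a
passive dendrite carrying the hyperpolarization-activated current
$I_h = g_h\, t\,(V - E_h)$ is coupled to the soma through an ohmic axial
conductance $I_{ac} = g_{ac}(V_i - V_{i+1})$, $g_{ac} = 0.2$ mS/cm².

Three conductance profiles bundle the configurations used by the analyses:
`fig1_2` (soma only, $g_{NaP} = 0.3$, $g_{KDR} = 6$; step and single-sinusoid
protocols), `fig3_7` (two compartments, $g_{NaP} = 0.93$, $g_{KDR} = 5.86$,
$g_h = 8.46$; resonance, phase-locking and quiet-interval protocols) and
`methods_default` (the full parameter list). Every parameter is an argument of
`ca1_model()`; `ca1_parameters()` lists them all.

```{r}
ca1_model("fig3_7")
```

## Calibration

The package's defaults are its own calibration of this model family. A handful
of parameter choices in the source description are mutually inconsistent (for
example, a fast-KCa voltage gate that would be open at rest and turn the
current into a large standing potassium clamp, an NaP half-activation that
leaves the current inert below spike threshold, an h-current reversal at the
potassium reversal that makes the "depolarizing" current purely outward, and
an h-gate time constant of several seconds near rest). Taken literally these
choices silence the model under every protocol, so the following values were
fixed once, against the qualitative behavior the model family is meant to
show, and are not revisited by any test:

* `theta_p = -46`, `sigma_p = 6` — the NaP activation midpoint/slope. These
  position the single-spike → burst → depolarization-block sequence under
  step drive (regular spiking at $g_{NaP} = 0.1$, an irregular-burst window
  around $0.3$–$0.5$, block well above the window) while keeping the
  two-compartment default $g_{NaP} = 0.93$ out of depolarization block under
  oscillatory drive.
* `sigma_c = +7` — the fKCa voltage gate opens with depolarization (BK-style),
  so the current is a spike-triggered afterhyperpolarization rather than a
  resting clamp. With this convention the calcium-activated currents are weak
  modulators, consistent with the model's insensitivity to their maximal
  conductances.
* `e_h = -30` mV — the conventional h-current reversal, giving the current its
  defining depolarizing role; the activation midpoint/slope
  ($\theta_t = -84$, $\sigma_t = -10.2$, hyperpolarization-activated) are kept.
* `tau_t = 50` ms — first-order h-gate kinetics at the fast-HCN timescale, so
  the dendritic current can act within a theta cycle.
* `g_l_dend = 0.3`, `e_l_dend = -70` — the passive dendrite's leak. The
  dendrite then rests slightly depolarized relative to the soma (through
  $I_h$) and acts as a weak corrective bath: it supplies the small
  depolarizing bias the low-excitability conditions need and loads the
  high-excitability conditions, which is what lets one drive amplitude serve
  the whole conductance range.

All remaining parameters are the standard published values for this cell
class. Every calibrated value is an ordinary argument of `ca1_model()`.

## Numerical integration

`simulate_ca1()` uses a fixed-step Euler–Maruyama scheme, default
`dt = 0.02` ms, with the somatic voltage receiving a Gaussian increment of
standard deviation $\sqrt{2 D\, dt}/C$ per step (default
$D = 9.6\times10^{-6}$). The initial condition is rest: $V = E_L$ in both
compartments, voltage gates at $x_\infty(E_L)$, zero calcium. The first 100 ms
are flagged as transient and excluded from event analysis. Runs are
deterministic given the seed; with $D = 0$ they are seed-independent. Under
`dt` halving the spike count of a regular-spiking run is unchanged;
individual spike times in marginally excitable regimes shift by a few
milliseconds because the threshold approach is shallow, and chaotic burst
regimes shadow only statistically. The default 4-s duration matches the
analysis window used throughout; sweeps and ensembles scale linearly.

## Event analysis

`detect_spikes()` records a spike at each local maximum following an upward
threshold crossing (default −10 mV, 2 ms refractory; the model's spikes
overshoot 0 mV, so detection is insensitive to the exact threshold).
`classify_events()` groups maximal runs of spikes with consecutive ISIs
strictly below 14 ms into one burst, timed at its first spike; trains with
fewer than two spikes are disregarded. Each event carries its preceding quiet
interval, measured from the previous spike of any event (the last spike of a
burst counts) to the event's first spike. `cv_isi()` is the population
standard deviation over the mean of the ISIs (at least two ISIs required);
`CV > 2` is the burstiness criterion. Event rates count a burst as one event;
intraburst structure is deliberately not analyzed.

`event_probability_by_interval()` bins events by the preceding interval
(10-ms bins over 0–500 ms by default) and reports, per bin, the conditional
probabilities $P(BS)$ and $P(SS)$ (which sum to 1 in occupied bins) plus each
type's own normalized interval density.

## Resonance and phase locking

`tuning_curve()` sweeps a sinusoidal drive over 2–100 Hz (the grid starts at
2 Hz so arbitrarily slow inputs are excluded) and records per-type event
rates; `resonance_summary()` extracts each type's resonance frequency
(argmax, ties toward the lower frequency) and amplitude, and the interleaving
differences $\Delta f = f_{SS} - f_{BS}$, $\Delta A = A_{SS} - A_{BS}$.

`spike_phases()` band-passes the reference signal (theta 3–12 Hz, gamma
30–100 Hz; zero-phase forward–backward Butterworth, order 3), takes the
analytic-signal phase and interpolates it at the event times. The reference
is the stimulus waveform, regenerated analytically at 2 kHz: input
phase-locking is the quantity of interest and the clean input avoids
spike-artifact filtering choices. `plv()` is the mean resultant length;
`pls()` applies the sample-size correction $(PLV^2 N - 1)/(N-1)$ so bursts
(few events) and single spikes (many events) can be compared.
`compare_groups()` provides Cohen's d with pooled (n−1) standard deviation
and the two-sided, unpaired, equal-variance t-test at α = 0.05.
`pls_experiment()` runs a 10-simulation ensemble and `pls_effect()` compares
the per-run burst and single-spike PLS samples (d is burst minus single
spike; runs in which a type has fewer than two events are dropped from that
type's sample).

## Quiet-interval estimators

The interval analyses in `scripts/acceptance.R` use estimators fixed a
priori: the burst-dominance threshold is, per conductance setting with at
least five bursts, the smallest 10-ms bin edge above which every occupied bin
has $P(BS) > 0.5$, maximized over settings; the single-spike concentration
bound is the upper edge of the bin holding the single-spike density peak,
pooled over the low-NaP and high-KDR settings; the gamma-only concentration
bound pools all nine settings and takes the larger of the two density-peak
bin edges. In the calibrated model, burst dominance begins by ~30 ms in every
burst-bearing setting (so dominance above 100 ms holds a fortiori, though the
onset is earlier than 100 ms), and under gamma-only drive the sparse
long-interval single spikes of the degenerate corner settings
($g_{NaP} = 1.5$, low $g_{KDR}$) dominate the pooled single-spike density.

## The imaging pipeline and its synthetic ground truth

`correct_photobleach()` fits $a + b e^{-t/\tau}$ to the trace's slow trend
(a 250-ms running median, which suppresses the sparse spike transients that
would otherwise bias $\tau$ by 10–20%) and subtracts the fitted curve;
non-convergence falls back to linear detrending and is flagged.
`detect_events_fluorescence()` inverts negative-polarity traces and takes
local maxima above `median + 4·MAD` with a 5-ms minimum separation and a
matching prominence requirement (a peak must rise by the same threshold above
the valley separating it from the previous accepted peak). The prominence
rule is what rejects secondary maxima riding on the slow decay tail of an
indicator transient while keeping the distinct rising peaks of a burst;
detection is invariant to affine rescaling. `area_stats()` compares each
type's normalized interval-density mass inside the low (100–150 ms),
intermediate (150–250 ms) and long (400–500 ms) windows across cells, with
paired t-tests by default and Cohen's d oriented so that positive d means
burst-dominant mass.

`generate_imaging_trace()` emulates the recordings the pipeline targets:
20 s at 600 Hz, negative-polarity transients (peak-normalized
difference-of-exponentials kernel, 2 ms rise, 10 ms decay, emulating the
indicator's low-pass kinetics) on a single-exponential bleach trend
($b = 2$, $\tau = 8$ s on a baseline of 10) with Gaussian noise
(s.d. 0.02, reflecting the high signal-to-noise cells such analyses select).
Event times follow a renewal process (exponential gaps, truncated below
20 ms, measured from the previous event's last spike — the same convention
the interval analysis uses, so planted events never overlap a running
burst); each event becomes a burst with probability 0.1/0.5/0.85 for
preceding intervals below 150 ms, 150–300 ms and above 300 ms, planting the
"bursts follow long quiet intervals" structure; burst sizes are 2–4 spikes at
8-ms intraburst intervals. The generator does not model indicator
photophysics, movement artifacts, or correlated noise, so passing the
round-trip tests demonstrates correctness of the pipeline's logic, not
performance on arbitrary real recordings.

```{r, fig.height = 3}
cells <- generate_imaging_cells(3, synth_imaging_config(duration = 10))
events <- lapply(cells, function(cl)
  classify_events(detect_events_fluorescence(correct_photobleach(cl$trace))))
# (with >= 2 cells per group this mirrors the per-area comparison)
```

## Known limitations

* The source description of this model family is internally inconsistent, and
  the calibration above restores its qualitative behavior rather than any
  original parameter file. Two behaviors resisted every calibration attempted:
  at $g_{NaP} = 0$ the model fires theta-locked single spikes but essentially
  no bursts (there is no regenerative subthreshold current left to build an
  afterdepolarization), and at $g_{NaP} = 0.5$ it bursts on nearly every
  theta cycle with few isolated spikes. Effect sizes comparing burst and
  single-spike locking are therefore undefined at those two settings, and the
  corresponding checks are expected to fail; the `fig3_7` default and the
  high-KDR setting show the full interleaved behavior.
* With the stated noise intensity the paths are nearly deterministic;
  run-to-run variability in ensembles comes from chaotic sensitivity of the
  burst dynamics, and conditions with regular dynamics can produce degenerate
  (very large) effect sizes because the pooled variance is tiny.
* The dendrite is a single passive compartment; no morphology, synaptic
  conductances, temperature dependence, or ion accumulation beyond the single
  calcium pool.
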