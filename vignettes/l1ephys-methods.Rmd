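---
title: "Methods: intrinsic properties, subset-screen clustering and connectivity of L1 interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic properties, subset-screen clustering and connectivity of L1 interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1ephys)
```

## Scope and model

Cortical Layer 1 interneurons (L1INs) come in three morphological types —
neurogliaform cells (NGC), elongated NGCs (eNGC) and single-bouquet-cell-like
(SBC-like) cells — and two dominant firing patterns, late-spiking (LS) and
non-late-spiking (NLS), distinguished by the delay to the first action
potential at just-suprathreshold drive. This package implements the full
quantitative chain used to characterize these cells from whole-cell
recordings:

1. extraction of 12 intrinsic electrophysiological properties from
   current-clamp sweeps;
2. LS/NLS classification;
3. Ward hierarchical clustering over an exhaustive screen of all
   $2^{12}-1 = 4095$ non-empty feature subsets, tested for association with
   morphology by Pearson chi-squared and validated by permutation;
4. paired-recording connectivity (gap-junction coupling coefficients,
   unitary IPSC detection) and optogenetic inhibition metrics.

Because raw recordings for the original dataset are not publicly deposited,
the package ships a synthetic-data module with known ground truth; every
analysis stage is validated against it.

## The twelve intrinsic properties

All sweeps are uniformly sampled (default 10 kHz) with times in ms, voltages
in mV, currents in pA. The canonical feature order used for subset masks is
given by `canonical_features()`: resting Vm, spike threshold, spike peak
amplitude, spike half-width, first spike latency, maximum rise slope, AHP
amplitude, AHP duration, input resistance, membrane time constant, cell
capacitance, depolarizing hump. The nine-feature mask `"111100101111"`
therefore decodes to {resting Vm, threshold, peak amplitude, half-width, AHP
amplitude, input resistance, time constant, capacitance, hump}.

Definitions (each a separate extractor function):

* **Resting Vm** — mean of the pre-onset baseline (>= 100 ms required).
* **Input resistance** — Ohm's law on the steady-state response to a
  −20 pA, 0.5 s step; the steady deflection is the mean of the final 100 ms
  of the step minus baseline. A drift check warns when the last 100 ms are
  not flat.
* **Membrane time constant** — time from step onset to the first crossing of
  $1 - 1/e$ of the steady deflection, linearly interpolated between samples.
* **Capacitance** — $C = \tau / R$ (ms/MΩ → nF, reported in pF). The ratio
  is forced by dimensional analysis.
* **Spike threshold** — the first point before a spike peak where the second
  derivative of the voltage exceeds three times its SD over a reference
  window. The reference window is 10 ms of pre-upstroke trace ending 3 ms
  before the peak; an absolute floor of 20 mV/ms² guards noiseless traces
  whose reference SD is numerically zero. Candidate peaks are local maxima
  above 0 mV preceded by an upstroke faster than 10 mV/ms.
* **Peak amplitude / half-width / max rise slope** — peak minus threshold;
  time between the interpolated crossings of threshold + amplitude/2;
  maximum central-difference dV/dt between threshold and peak.
* **Depolarizing hump** — maximum potential within 200 ms of the onset of a
  just-below-threshold step minus the mean over the final 300 ms of the
  step. Positive values indicate the early transient overshoot typical of
  NLS cells; the value is reported unclipped.
* **First-spike latency** — onset of the just-suprathreshold step to the
  threshold time of the first spike. When several step amplitudes are
  available, the just-suprathreshold sweep is the smallest step evoking at
  least one spike.
* **AHP amplitude / duration** — after a +300 pA step: steady-state
  potential (mean of the last 200 ms of the recording, required flat) minus
  the minimum within 400 ms of offset; duration until the potential first
  enters and stays within 0.5 mV of steady state for 50 ms. The 0.5 mV /
  50 ms band quantifies the otherwise loose notion of "returned to steady
  state".

**LS/NLS cutoff.** No standard numeric cutoff exists for "late" spiking. The
default is 400 ms on a 2 s step, exposed as `ls_cutoff_ms` everywhere and
reported with every classification: reported per-subtype mean latencies
(≈ 1037 ms for NGC vs ≈ 559 ms for SBC-like) overlap enough that the cutoff
materially matters. Burst-spiking (BS) detection is available (≥ 3 spikes in
a configurable onset window) but BS cells are excluded from clustering by
default, mirroring their rarity (≈ 1%) in the population this package
targets.

## Synthetic data

`simulate_sweep()` integrates a single-compartment membrane equation by
forward Euler at the sampling rate (default 10 kHz; adequate for the
millisecond-scale kinetics simulated here):

$$C\,\dot V = (E_L - V)/R + I_{inj}(t)
  - g_K\, m(V)\, a\, (V - E_K)
  + g_h\, m(V)\, b\, (0 - V)
  + g_L \Delta_T e^{(V - V_T)/\Delta_T} - g_w w (V - E_K)$$

* The **slow K⁺ gate** $a$ starts fully available and inactivates with time
  constant `kslow_tau_ms` (default 300 ms) whenever the cell is depolarized
  ~10 mV above rest (sigmoidal activation $m$). While available it holds a
  just-suprathreshold response below threshold; the first spike occurs only
  after the conductance has inactivated. This produces late spiking
  mechanistically — latency varies continuously with `kslow_conductance_nS`
  and with drive — rather than from a fitted template, consistent with the
  transient-K⁺ account of LS firing.
* The **hump gate** $b$ likewise inactivates (default 60 ms) and, while
  available, passes a transient inward current. Its reversal is set at 0 mV
  (a mixed-cation/window-current approximation): a reversal near rest could
  only produce an outward pull at the depolarized potentials where the hump
  is measured, so it could not generate the overshoot it is meant to model.
* **Spikes**: the exponential term sharpens the approach to threshold; once
  $V$ crosses $V_T$ a stereotyped spike body (raised sine with configurable
  peak and width, default half-width 1.2 ms) is pasted and $V$ is reset.
  The analytic body gives the shape extractors exact ground truth.
* **AHP**: each spike increments an adaptation conductance $w$ (decay
  150 ms), producing a post-train undershoot.
* **Noise** in single-cell sweeps is Ornstein–Uhlenbeck with stationary SD
  `noise_sd_mV`. In `simulate_pair()` the added noise is instead white
  recording noise: the connection detectors compare event-triggered-average
  windows against a baseline-SD criterion, which presumes independent
  baseline samples; slow membrane noise would require a whitening detector
  instead and is not what the criterion targets.

Euler at 0.1 ms shortens the effective time constant by about $dt/(2\tau)$
(≈ 0.4 % at τ = 12 ms), well inside the 2 % recovery tolerance used in the
tests.

`sample_feature_table()` draws per-subtype multivariate-normal feature
vectors. The preset `table_preset_spec()` uses the reported per-subtype
means with SDs reconstructed as $SEM \sqrt n$ from the published summaries
(n = 11/12/10); within-subtype correlations default to 0 since none are
reported. The generator emulates per-subtype marginal distributions only: it
does not reproduce feature correlations, recording artifacts, or
non-normality of latency distributions, so passing recovery tests validate
the pipeline's mechanics, not distributional realism of real recordings.

Paired recordings join two such cells with a gap junction whose conductance
is solved from the target coupling coefficient ($g = cc \cdot g_{L2}/(1-cc)$,
from the steady-state two-cell balance) and/or a GABAergic synapse that adds
an outward difference-of-exponentials current (rise 0.3 ms, decay 8 ms) to
the +6 mV voltage-clamp trace at a configurable latency (default 2.6 ms)
after each presynaptic threshold crossing. Optogenetic datasets draw eIPSC
amplitudes/latencies from the reported four target groups (L2/3 and L5/6
pyramidal neurons and interneurons), and pulse-train rasters fire with
probability 1 up to 20 Hz and $20/f$ above — the reported fidelity
behaviour.

## Clustering screen

`ward_cluster()` z-scores each selected feature (the 12 properties span mV,
ms, MΩ and pF; unstandardized Euclidean distances would be dominated by
input resistance — the flag `standardize` can disable this), builds Ward
linkage (`ward.D2`) on Euclidean distances, and cuts the tree into exactly
`n_clusters` groups (default 3). Group labels are canonicalized — 1..k by
descending size, ties by ascending mean of the first selected feature — so
assignments are reproducible and invariant to cell order; the chi-squared
association is label-invariant in any case (property-tested).

`subset_screen()` runs this for every non-empty feature subset (4095 for 12
features), followed by a Pearson chi-squared test (no continuity
correction) of the groups × morphology table over the labelled cells;
unlabelled cells participate in clustering but not in the test. Expected
counts below 5 are tolerated deliberately — the association statistics this
package reproduces were computed on 33 labelled cells where small expected
counts are unavoidable — and can be surfaced with `warn_expected`.
Per-subset failures (e.g. degenerate tables) are recorded in the result row
rather than aborting the screen. Squared per-feature distance matrices are
precomputed once, so the full 4095-subset screen on a 104 × 12 table takes
a few seconds.

`weight_and_select()` interprets "weighing each property in the significant
subsets" as frequency: a feature's weight is the number of significant
subsets containing it. The top `target_subset_size` (default 9) features by
weight (ties broken by canonical order) form the selected mask; coverage is
the number of significant subsets fully contained in it. The function also
reports whether adding the next-ranked feature loses the significance of
the selected subset's own association. The weighting rule is an
interpretation — the original description does not pin it down — and is
isolated in one function so alternatives can be substituted.

`permutation_validation()` implements both published controls: variant
`"screen"` shuffles every feature column independently across cells and
reruns the entire subset screen on the shuffled data; variant `"selected"`
repeats (default 1000×) the shuffle–cluster–test cycle on one fixed mask and
reports the fraction of shuffles reaching significance, which should match
α on null data.

## Statistics

Chi-squared tests (independence and goodness-of-fit) report Cohen's
$w = \sqrt{\chi^2/N}$. One-way ANOVA reports $\eta^2 = SS_b/SS_{tot}$, with
Tukey HSD for post-hoc pairs. `anova_from_summary()` reconstructs the ANOVA
from per-group mean/SEM/n ($SD_i = SEM_i\sqrt{n_i}$), which is what lets
published summary tables be checked without raw data; it agrees with
`anova_oneway()` to numerical precision when fed a dataset's own summaries.
Unpaired t-tests are pooled-variance Student tests by default (Welch by
flag) with $d = \Delta m / SD_{pooled}$; paired tests use
$d = \bar d / SD_d$. p-values come from the standard reference
distributions throughout.

## Connectivity measurements

The coupling coefficient is $\Delta V_{post}/\Delta V_{stim}$ with both
deflections measured over the final 200 ms of a 2 s subthreshold step; a
deflection below 1 mV in the stimulated cell flags the estimate unreliable.
Connection detection uses event-triggered averages over evoked APs (≥ 3
clean events required): a connection is called when the peak deflection
within the detection window (5 ms electrical, 10 ms chemical) exceeds 5 ×
the SD of the average's pre-event baseline. Onset latency is the
10 %-of-peak crossing; for electrical pairs the reference level is the
average's value at the AP time itself, because a gap junction also passes
the subthreshold drive preceding the spike and would otherwise drag the
onset before the event. These thresholds are configurable defaults standing
in for what was originally a visual/pharmacological judgement. eIPSC
quantification smooths the clamp current with a 1 ms centred moving average
before peak measurement (the synaptic current is far slower than single
samples), then applies a 3 × baseline-SD no-response criterion.

## Problem sizes and numerical choices

The bundled validation runs use: 104-cell tables for screen enumeration (the
reported dataset size), 33-cell planted tables (11/12/10 — the reported
morphologically registered counts) with 4 informative features at 3
pooled-SD spacing for recovery checks over 100 generator seeds, 1000
shuffles for permutation levels, and 1000 simulated unconnected pairs for
detector false-positive rates. Deterministic behaviour under a seed is part
of every generator's contract; generator seeds are isolated from the global
RNG state.

Known limitations: the simulator is a single compartment with stereotyped
spikes (no spike-shape diversity, bursting or sag); planted-cluster recovery
uses spherical within-class covariance; the chi-squared approximation at
n = 33 with expected counts < 5 is approximate, which is exactly why the
permutation controls are part of the method; and the LS/NLS cutoff remains a
reporting choice rather than a biological constant.
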