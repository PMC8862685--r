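---
title: "High-frequency transmission through paired feed-forward excitation and delayed inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-frequency transmission through paired feed-forward excitation and delayed inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffeisim)
```

## The scientific question

Neuronal membranes low-pass filter their inputs: with a 10 ms membrane
time constant, current fluctuations much above ~20 Hz barely move the
membrane potential, yet sensory pathways demonstrably relay information at
50–100 Hz and above. A recurring anatomical motif offers an explanation:
long-range excitatory projections are often paired with a slightly delayed
feed-forward inhibitory copy of the same signal — at the retinogeniculate
triad synapse through a dendro-dendritic contact, and at thalamocortical,
intercortical and hippocampal projections through feed-forward
interneurons. The paired input delivers a brief, large net current pulse:
the excitation opens a short window in which the cell can fire before the
inhibitory copy shuts it; the residual inhibition decays quickly enough
that the cell is ready for the next pulse. `ffeisim` simulates this motif
(FFEI) against feed-forward excitation alone (FFE) and quantifies
transmission spectrally.

## Model

**Membrane.** Leaky integrate-and-fire neurons,

$$\frac{dV_m}{dt} = -\frac{V_m - V_e}{\tau_m}
  - \frac{R_m}{\tau_m}\sum_n \alpha_n P_n(t)\,(V_m - V_{syn,n})
  + \frac{R_m}{\tau_m} I_{inj}(t),$$

integrated by forward Euler (default $\Delta t = 0.1$ ms; selected
experiments use 0.02 ms). When $V_m$ reaches threshold a spike is recorded
and $V_m$ is set to $V_{reset}$ on the same step; integration resumes from
the reset on the next step. Defaults: $\tau_m = 10$ ms, $R_m = 10$
M$\Omega$, $V_e = -75$ mV, $V_{reset} = -80$ mV, $V_{thresh} = -40$ mV
(interneurons in the cortical circuit: $-48$ mV). Units are fixed
repo-wide as ms / mV / M$\Omega$ / µS / nA, under which
$\mathrm{mV} = \mathrm{M\Omega}\cdot\mathrm{nA}
 = \mathrm{M\Omega}\cdot\mathrm{\mu S}\cdot\mathrm{mV}$.

**Synapses.** Conductance kernels are peak-normalized differences of
exponentials; a presynaptic spike at $s$ contributes
$P_{max} B (e^{-\Delta t_j/\tau_{fall}} - e^{-\Delta t_j/\tau_{rise}})$
for $\Delta t_j = t - (s + \Delta) \ge 0$, with $B$ chosen so the kernel
peaks at $P_{max}$ (analytic peak time
$t^* = \frac{\tau_f \tau_r}{\tau_f - \tau_r}\ln\frac{\tau_f}{\tau_r}$).
The FFEI motif drives an excitatory kernel and, after delay $\Delta$
(default 1 ms), an inhibitory kernel ($V_{syn} = -80$ mV, current scaled
by $\alpha = 1.25$) from the *same* spike train. When the inhibitory fall
time differs from the excitatory one, the inhibitory peak is set by
equating single-spike kernel integrals,
$P_{max,i} = P_{max,e}\,(B_e/B_i)\,
 (\tau_{fall,e}-\tau_{rise,e})/(\tau_{fall,i}-\tau_{rise,i})$
(`balanced_inhibitory_peak()`), which reproduces all published weight
pairs to three significant figures.

**Short-term depression.** Two multiplicative resources per synapse:
amplitude $A = A_0 D_1 D_2$; after each spike $D_i \leftarrow D_i d_i$,
recovering exponentially to 1 with $\tau_{d_i}$. Fitted constants for
AMPA, NMDA and GABA receptors ship in `model_parameters()$depression`
(recovery times are seconds in the sources, stored here in ms).

**Inputs.** Feed-forward drive is an inhomogeneous Poisson process with
rectified sinusoidal rate $r(t) = \mathrm{rectify}(PR \sin 2\pi F t)$
($PR = 100$ Hz except where noted); per 0.1 ms step a spike occurs iff a
uniform draw is below $r(t)\,dt$. Background activity is modeled as
$N$ independent Poisson inputs at the balanced rate $FR = PR/\pi$
(the mean of the rectified sine), 31.83 Hz for $PR = 100$.

**Spectral metrics.** Spiking output is converted to a rate signal (a
spike contributes $1/\Delta t$ Hz to its step) and measured by the scaled
Fourier magnitude
$FC_F = \left|\frac{2\Delta t}{L}\sum_t R(t) e^{-2\pi i F t}\right|$
(units Hz; at $F = 0$ this is twice the mean rate). Specificity is
$FC_F / FC_{avg}$, where $FC_{avg}$ averages $FC$ over the grid
$F = 0, 1/L, \dots, 1/\Delta t$ (one FFT of the per-step counts; the
above-Nyquist half consists of conjugate aliases, so including it matches
a Nyquist-limited mean up to the endpoint terms — both conventions are
exposed, the default includes $F = 0$ since the stated grid names it).
Each metric is averaged across trials separately (10-trial protocol). The
half-maximum cutoff is the frequency where a transmission curve first
falls to half its 5 Hz reference, interpolated linearly in
$\log F$ — the paper plots but does not define the interpolation, so the
log-linear choice is ours; the cutoff is invariant to rescaling the curve.

## Architectures

```{r architectures, eval = FALSE}
run_triad(F = 50, mode = "ffei")        # 1 input, kernel-level inhibition
run_current_injection(F = 50)           # membrane-filtering control
run_multilevel(F = 5, mode = "ffei")    # 4-level chain + 50-input noise/level
run_cortical_circuit(F = 20)            # 100 inputs, explicit LIF interneuron
run_xor(F = 5, mode = "mixed")          # paired mixed-sign XOR circuit
run_receptor_mixture("AMPA+NMDA+GABA")  # explicit receptor kinetics
```

Two inhibition regimes are deliberately contrasted. The triad model has
*kernel-level* inhibition — the inhibitory conductance is driven directly
by the input train with delay $\Delta$, abstracting the dendro-dendritic
contact with no interneuron spike threshold. The cortical circuit has
*circuit-level* inhibition: 100 inputs drive an excitatory cell (2 nS
each) and an explicit LIF interneuron (0.6 nS each) whose spikes gate a
100 nS inhibitory conductance onto the excitatory cell; no delay
parameter exists there — the lag emerges from interneuron dynamics, which
is exactly why its membrane time constant limits the circuit's cutoff.

## Design choices where the sources are open

* **Initial condition** $V_m(0) = V_e$: transients die within
  $\sim 5\tau_m$ and analyses either average seconds-long runs or discard
  the first second (depressing synapses).
* **Fig-7-style "GABA-like" arm**: the tables give inhibitory amplitudes
  but no separate inhibitory kinetics, so the inhibitory arm is a delayed
  copy of *both* excitatory kernels (AMPA- and NMDA-kinetics) at the
  listed amplitudes, reversal $-80$ mV.
* **Multilevel inter-level projections** use direct paired kernels with
  $\Delta = 1$ ms, $\alpha = 1.25$ (the strength tables list only
  $P_{max}$; whether $\alpha$ there is 1 or 1.25 is not printed).
* **Stepped-frequency inputs** restart the sine phase at 0 at each
  plateau boundary; spectra are computed per bin, so boundary phase has
  negligible effect.
* **Single-sign XOR "−" inputs** are the leading (inhibitory) kernel of
  the mixed-sign pair alone, at the single-sign weight.
* **Trial length** defaults to 5 s per frequency point (stated explicitly
  only for the depression experiments; elsewhere declared, not inferred).
* **Published weights, not re-calibration**: experiments use the printed
  per-figure weight tables verbatim rather than re-running the
  "adjust until ~75 Hz at 5 Hz" search.

## Numerical behavior worth knowing

**Forward Euler with strong synapses is bookkeeping-sensitive at
$\Delta t = 0.1$ ms.** The triad FFEI defaults (1.21 µS against a
10 M$\Omega$ membrane) put the cell within a few mV of threshold between
input events, and clustered input spikes push the summed conductance into
a regime where the Euler update overshoots around its equilibrium. The
per-event spike count then depends on exactly how the reset step is
accounted, and the mapping from synaptic weight to output rate at
$\Delta t = 0.1$ ms varies by tens of percent across equally plausible
bookkeepings (this package's convention, a variant that holds the reset
one extra step, and exponential-Euler integration give 5 Hz Fourier
coefficients of roughly 104, 70 and 42 Hz respectively at the default
weights). At $\Delta t = 0.02$ ms these differences vanish, and this
implementation reproduces the published fine-step calibration rows to
about 1% (e.g. $P_{max} = 1.67$ µS, $\alpha = 1.25$ gives
$FC_5 \approx 75$ Hz). We therefore keep the simplest stated convention
and read coarse-step absolute response levels with that caveat; relative
comparisons (FFEI vs FFE folds, cutoff ratios, monotonic trends) are
robust across bookkeepings.

Other numerics: conductance traces are built by FFT convolution of the
per-step impulse sequence with the kernel (equivalent to direct
superposition to ~1e-12 and $O(n\log n)$); tiny negative round-off is
clamped to zero. Degenerate kernels ($\tau_{rise} \ge \tau_{fall}$) are
rejected rather than special-cased as alpha functions. Poisson generation
enforces $r\,dt < 1$. Sub-seeds for each (frequency, trial) cell are
derived deterministically from one master seed, so whole experiments are
reproducible and FFEI/FFE comparisons can share input realizations.

## What the generator emulates — and what it does not

Inputs are Poisson with the stated rate profiles: real retinal and
cortical spike trains have refractoriness, burstiness and adaptation that
are deliberately out of scope, as are Hodgkin–Huxley currents,
multi-compartment dendrites, NMDA magnesium block, stochastic vesicle
release and recurrent connectivity. Passing tests therefore show that the
*motif* behaves as described under idealized drive, not that any
particular biological circuit does.

## Problem sizes used by the shipped checks

The test suite runs scaled-down simulations (typically 2–5 trials of
2–5 s) for speed; the quantitative end-to-end checks use 5–10 trials of
5 s at the protocol's frequencies, and `scripts/acceptance.R` uses the
full 10-trial protocol throughout (about a minute of compute). Cutoff
estimates from flat transmission curves are noisy in the 5 Hz reference;
where a curve never halves within its sweep the top swept frequency is
reported as a censored lower bound (mirroring the published observation
that the weakest four-level FFEI pair has no cutoff in range).

## Known limitations

* Absolute coarse-step response levels inherit the bookkeeping
  sensitivity above; compare like with like.
* The half-maximum cutoff of a nearly flat curve is an ill-conditioned
  statistic; prefer more trials (or the normalized-transmission curve)
  when estimating it.
* The depression model is calibrated at the triad synapse; using the GABA
  constants for both GABA_A and GABA_B arms follows the source tables,
  not independent fits.
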