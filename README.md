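# ffeisim

Spiking-circuit simulations of **paired feed-forward excitation with
delayed inhibition (FFEI)** and spectral analysis of how well such
projections transmit high-frequency temporal information, compared with
feed-forward excitation alone (FFE).

Neuronal membranes low-pass filter their inputs (τ_m ≈ 10 ms), yet many
pathways relay 50–100 Hz signals. A common motif pairs each long-range
excitatory input with a slightly delayed inhibitory copy — the
retinogeniculate triad synapse, thalamocortical and hippocampal
feed-forward interneurons. The pair delivers a brief, large current pulse
that can fire the cell before inhibition arrives, effectively acting as a
value-plus-clock signal. `ffeisim` is for computational neuroscientists
who want to simulate this motif across circuit scales and quantify its
transmission bandwidth.

## Model core

Leaky integrate-and-fire neurons (forward Euler, dt = 0.1 ms default):

    dVm/dt = −(Vm − Ve)/τm − (Rm/τm) Σ_n αn Pn(t) (Vm − Vsyn,n) + (Rm/τm) I(t)

with conductance kernels P(t) built as peak-normalized differences of
exponentials, optional two-factor short-term depression
(A = A0·D1·D2, per-spike decrements, exponential recovery), and
inhomogeneous Poisson inputs with rectified sinusoidal rate
r(t) = rectify(PR·sin(2πFt)). Transmission is measured by the Fourier
coefficient of the output rate at the input modulation frequency,

    FC_F = | (2Δt/L) Σ_t R(t) e^(−2πi·F·t) |   (Hz),

its whole-spectrum mean FC_avg, the normalized transmission FC_F/FC_avg,
and the half-maximum cutoff (frequency where a curve halves relative to
its 5 Hz reference, log-interpolated).

Architectures: triad synapse (`run_triad`), direct current injection
(`run_current_injection`), four-level hierarchical network with per-level
background noise (`run_multilevel`), 100-input cortical circuit with an
explicit LIF interneuron (`run_cortical_circuit`), mixed-sign XOR circuit
(`run_xor`, with `expected_xor` ground truth), and explicit
AMPA/NMDA/GABA receptor mixtures with depression
(`run_receptor_mixture`). Published parameter tables ship in
`model_parameters()`.

## Worked example

Sweep the triad model in both configurations and compare:

```r
library(ffeisim)
freqs <- c(5, 20, 50, 100, 200)
ffei <- transmission_sweep(triad_runner("ffei", seed = 1), freqs, n_trials = 3)
ffe  <- transmission_sweep(triad_runner("ffe",  seed = 1), freqs, n_trials = 3)
print(ffei)
print(ffe)
cat(sprintf("FFEI/FFE Fourier-coefficient fold at 100 Hz: %.1f\n",
            ffei$fc_f[freqs == 100] / ffe$fc_f[freqs == 100]))
```

```
<transmission_curve> 5 frequencies, 3 trials each
 frequency_hz  fc_f fc_avg fc_norm
            5 90.39  5.196   17.26
           20 80.23  5.559   14.42
           50 94.23  5.952   15.81
          100 74.86  5.601   13.37
          200 68.46  5.407   12.59
half-maximum cutoff (fc_norm): NA Hz; (fc_f): NA Hz
<transmission_curve> 5 frequencies, 3 trials each
 frequency_hz   fc_f fc_avg fc_norm
            5 82.665  5.576  14.814
           20 39.796  4.446   8.948
           50 18.978  4.446   4.277
          100 11.033  4.375   2.517
          200  5.442  4.440   1.206
half-maximum cutoff (fc_norm): 27.06 Hz; (fc_f): 19.03 Hz
FFEI/FFE Fourier-coefficient fold at 100 Hz: 6.8
```

Read: the FFEI projection transmits with near-constant fidelity out to
200 Hz (its curve never halves within this sweep, hence `NA`), while the
excitatory-only projection is filtered above ~20 Hz; at 100 Hz the paired
projection carries ~7× the locked output. `fc_norm ≈ 1` would mean a
frequency-nonspecific output.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/ffei.R simulate --arch triad-ffei --set F=50 --trials 10 --seed 1 --out out_dir
Rscript inst/cli/ffei.R experiment --name fig5 --seed 1 --out out_dir
```

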