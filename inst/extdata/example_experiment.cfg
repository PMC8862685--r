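# Example experiment config for run_experiment() / the ffei.R CLI.
# One key = value per line; '#' starts a comment.
experiment = fig1
n_trials = 5
duration = 3000   # ms per trial
f_max = 300       # top of the log-spaced frequency sweep (Hz)
n_freqs = 10
tau_fall_i = 20   # inhibitory fall time constant (ms)
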