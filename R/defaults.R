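## Default amplitudes of the non-Hebbian excitatory plasticity terms and the
## slow-trace time constant.  These are the frozen output of the fixed-point
## calibration run against the default neuron model (see
## calibrate_orchestration() and the methods vignette): with the triplet
## amplitude fixed at A = 1e-3 and 80 presynaptic Poisson inputs at 10 Hz,
## (delta, beta) are solved so that the weight-drift curve -- with the
## trace-moment correction factors measured from the actual postsynaptic
## spike train and the operating value of w - wtilde sustained by the
## consolidation dynamics -- vanishes at 1 Hz and 30 Hz, the two published
## stable firing-rate fixed points.
.plastinet_default_beta <- 0.0975
.plastinet_default_delta <- 1.817e-5
.plastinet_default_tau_slow <- 0.2
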