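# plastinet

Spiking recurrent-network simulation of **orchestrated synaptic
plasticity**: a conductance-based integrate-and-fire network in which
excitatory synapses are governed simultaneously by

* **triplet STDP** — LTP on a postsynaptic spike,
  `Δw = A · z⁺_j · z_slow_i` (quadratic in the postsynaptic rate), and LTD
  on a presynaptic spike, `Δw = −B_i · z⁻_i` (linear in the postsynaptic
  rate);
* **heterosynaptic plasticity** — on a postsynaptic spike,
  `Δw = −β (w_ij − w̃_ij) (z⁻_i)³`; the cubed fast post trace times the
  triggering spike gives an effective fourth power of the postsynaptic
  rate, a *burst detector* that pushes every synapse on a bursting neuron
  back towards its reference weight `w̃`;
* **transmitter-induced plasticity** — `Δw = +δ` per presynaptic spike;
* **consolidation** — each reference weight descends a double-well
  potential while being dragged towards the current weight,
  `τ_c dw̃/dt = (w − w̃) − P w̃ (w_P/2 − w̃)(w_P − w̃)`,
  with stable wells at 0 and `w_P = 0.5` (20–60-min timescale);
* **Tsodyks–Markram short-term plasticity** on all excitatory synapses
  (`U = 0.2`), and
* **globally modulated inhibitory STDP**: pair-based updates
  `Δw = η · G(t) · z`, gated by `G = H − γ` where `H` low-pass filters all
  excitatory spikes (a secreted factor); Hebbian when the network is too
  active, depression-only when it is too quiet.

In expectation over Poisson trains the combined excitatory rule gives the
weight drift

```
dw/dt = A τ₊ τ_slow ν_pre ν_post² − B τ₋ ν_pre ν_post
        − β (w − w̃) ν_post E[(z⁻)³] + δ ν_pre
```

whose two *stable* zeros — near 1 Hz (transmitter-induced potentiation vs
LTD) and near 30 Hz (heterosynaptic depression vs LTP) — make single
synapses, and with them cell assemblies, bistable.  The package implements
the neuron and synapse models, the induction and stimulation protocols
(pairing, postsynaptic tetanization, stochastic pattern presentation,
directed subpopulation stimulation, consolidation blockade), network
construction, and the spike-train/weight-matrix analysis tools, with the
long simulation loop in compiled code (Rcpp).  Who is it for: modellers who
want to probe how non-Hebbian plasticity stabilises Hebbian learning
without running the original full-scale (4096+1024 neuron, multi-hour)
simulations.

## Worked example

The feed-forward bistability experiment: one neuron, 80 plastic synapses
driven at 10 Hz plus an 80-synapse 1-Hz control pathway, plasticity
enabled after one minute.  Started above the separatrix the output rate
converges to the elevated fixed point; started below, to the low one:

```r
library(plastinet)
hi <- run_single_neuron_bistability(initial_w = 0.35, duration = 600, seed = 1)
lo <- run_single_neuron_bistability(initial_w = 0.20, duration = 600, seed = 1)
c(upper = hi$summary$rate, lower = lo$summary$rate)
#>  upper  lower
#> 28.275  1.400
hi$summary$max_w                      # converged weights stay well below w_max = 5
#> [1] 0.7228432
hi$summary$clamp_events_after_burnin  # the bound is never hit
#> [1] 0
```

`28.3 Hz` and `1.4 Hz` are the two stable firing-rate fixed points created
by the interplay of triplet LTP/LTD with the heterosynaptic and
transmitter-induced terms; `max_w` shows that the upper state is held by
the plasticity fixed point itself, not by the hard weight bound.

The drift-curve view of the same physics:

```r
pp <- calibrate_exc_amplitudes()$params   # Poisson-moment calibration
drift_fixed_points(pp, nu_pre = 10, d = 0.2)
#> [1]  0.9925815 30.0000000
```

A command-line front end for the protocols is installed at
`inst/cli/plastinet` (`plastinet run bistability_high --seed 1 --out dir/`,
`plastinet calibrate`, `plastinet fixtures patterns`,
`plastinet analyze`).

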