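#' Parameters of globally modulated inhibitory plasticity
#'
#' Inhibitory synapses onto excitatory neurons follow a symmetric pair-based
#' STDP rule whose sign and magnitude are set by a global factor
#' `G(t) = H(t) - gamma`, where `H(t)` is a low-pass filter of all spikes in
#' the excitatory population (a secreted chemical signal) and `gamma` is its
#' target value.  On a postsynaptic (excitatory) spike every afferent
#' inhibitory synapse changes by `eta * G * z_pre`; on a presynaptic
#' (inhibitory) spike the synapse changes by `eta * G * z_post`.  With
#' `G > 0` (network too active) the rule is Hebbian and inhibition grows;
#' with `G < 0` every update is non-positive ("depression only"), releasing
#' inhibition.  No per-neuron target rate is enforced -- only the
#' population-level constraint `H ~ gamma`.
#'
#' `H` is normalised so that it estimates the mean per-neuron rate of the
#' excitatory population in Hz: each excitatory spike increments `H` by
#' `1 / (N_exc * tau_H)` and `H` decays with time constant `tau_H`.
#'
#' @param eta learning rate.
#' @param tau_z common time constant (s) of the pre/post traces.
#' @param tau_H filter time constant (s) of the secreted factor.
#' @param gamma target value of `H` (Hz).
#' @return object of class `inh_plasticity_params`.
#' @export
inh_plasticity_params <- function(eta = 1e-4, tau_z = 20e-3, tau_H = 10,
                                  gamma = 3) {
  if (eta < 0) stop("'eta' must be non-negative")
  if (tau_z <= 0 || tau_H <= 0) stop("time constants must be positive")
  structure(list(eta = eta, tau_z = tau_z, tau_H = tau_H, gamma = gamma),
            class = "inh_plasticity_params")
}

#' Advance the global secreted factor by one time step
#'
#' `H` decays by the exact exponential factor and is incremented by
#' `n_spikes / (n_exc * tau_H)`, where `n_spikes` is the number of
#' excitatory spikes emitted in this step.  In steady state `H` equals the
#' mean per-neuron rate of the excitatory population in Hz.
#'
#' @param H current value of the secreted factor.
#' @param n_spikes excitatory spike count in this step.
#' @param dt time step (s).
#' @param params an [inh_plasticity_params()] object.
#' @param n_exc size of the excitatory population.
#' @return list with updated `H` and the modulation `G = H - gamma`.
#' @export
step_global_factor <- function(H, n_spikes, dt, params, n_exc) {
  H <- H * exp(-dt / params$tau_H) + n_spikes / (n_exc * params$tau_H)
  list(H = H, G = H - params$gamma)
}

#' Pair-based inhibitory weight update
#'
#' Event update of inhibitory weights: `w <- max(0, w + eta * G * z)`, where
#' `z` is the partner trace (postsynaptic trace on a presynaptic spike,
#' presynaptic trace on a postsynaptic spike).
#'
#' @param w inhibitory weight(s), non-negative.
#' @param z partner trace value(s).
#' @param G current global modulation.
#' @param params an [inh_plasticity_params()] object.
#' @return updated weight(s), clamped at 0 from below.
#' @export
inh_pair_update <- function(w, z, G, params) {
  pmax(0, w + params$eta * G * z)
}
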