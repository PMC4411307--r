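#' Conductance-based integrate-and-fire neuron parameters
#'
#' Leaky integrate-and-fire neuron with conductance-based synaptic input,
#' spike-triggered adaptation and a dynamic threshold.  All conductances are
#' dimensionless (in units of the leak conductance); voltages in volts,
#' times in seconds.  The membrane obeys
#' \deqn{\tau_m \dot U = (U_{rest} - U) + g_{exc}(E_{exc} - U)
#'       + g_{gaba}(E_{inh} - U) + (g_a + g_{a2})(E_{adapt} - U) + I_{ext},}
#' where the excitatory conductance is the AMPA/NMDA mix
#' `g_exc = alpha * g_ampa + (1 - alpha) * g_nmda` and the NMDA component
#' low-pass filters the AMPA one: `tau_nmda * dg_nmda/dt = g_ampa - g_nmda`
#' ("slowly rising and decaying").  `g_ampa` jumps by `w * r` on delivered
#' excitatory spikes (release factor `r` from STP), `g_gaba` by `w` on
#' inhibitory spikes, and the adaptation conductance(s) by `delta_a`
#' (`delta_a2`) on the neuron's own spikes.  A spike is emitted when
#' `U >= theta`; then `U -> U_reset`, the dynamic threshold jumps by
#' `theta_jump` (relaxing back to `theta_rest` with `tau_thr`, implementing
#' refractoriness), and adaptation increments are applied.  The voltage is
#' floored at `E_inh` to prevent Euler overshoot.
#'
#' The slow second adaptation conductance (`delta_a2 > 0`, `tau_adapt2`
#' around 20 s) mimics the long-lasting adaptation used to destabilise
#' delay activity on the tens-of-seconds scale; it is off by default.
#'
#' @param tau_mem membrane time constant (s).
#' @param U_rest,U_reset resting and reset potential (V).
#' @param theta_rest resting threshold (V).
#' @param theta_jump threshold jump at a spike (V).
#' @param tau_thr threshold relaxation time constant (s).
#' @param E_exc,E_inh,E_adapt reversal potentials (V).
#' @param tau_ampa,tau_nmda,tau_gaba,tau_adapt,tau_adapt2 conductance time
#'   constants (s).
#' @param delta_a,delta_a2 adaptation conductance jumps per spike.
#' @param alpha AMPA weight in the excitatory conductance mix.
#' @param I_ext constant external drive, expressed in volts (current divided
#'   by leak conductance).
#' @return object of class `neuron_params`.
#' @export
neuron_params <- function(tau_mem = 20e-3,
                          U_rest = -70e-3, U_reset = -70e-3,
                          theta_rest = -52e-3, theta_jump = 100e-3,
                          tau_thr = 5e-3,
                          E_exc = 0, E_inh = -80e-3, E_adapt = -80e-3,
                          tau_ampa = 5e-3, tau_nmda = 100e-3,
                          tau_gaba = 30e-3,
                          tau_adapt = 1, delta_a = 0.05,
                          tau_adapt2 = 20, delta_a2 = 0,
                          alpha = 0.9, I_ext = 0) {
  taus <- c(tau_mem, tau_thr, tau_ampa, tau_nmda, tau_gaba, tau_adapt,
            tau_adapt2)
  if (any(taus <= 0)) stop("all time constants must be positive")
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (delta_a < 0 || delta_a2 < 0) stop("adaptation jumps must be non-negative")
  structure(list(tau_mem = tau_mem, U_rest = U_rest, U_reset = U_reset,
                 theta_rest = theta_rest, theta_jump = theta_jump,
                 tau_thr = tau_thr, E_exc = E_exc, E_inh = E_inh,
                 E_adapt = E_adapt, tau_ampa = tau_ampa,
                 tau_nmda = tau_nmda, tau_gaba = tau_gaba,
                 tau_adapt = tau_adapt, delta_a = delta_a,
                 tau_adapt2 = tau_adapt2, delta_a2 = delta_a2,
                 alpha = alpha, I_ext = I_ext),
            class = "neuron_params")
}

#' One step of Poisson spiking
#'
#' Each unit spikes independently with probability `rate * dt` in this step
#' (requires `rate * dt << 1`).  Uses R's global RNG stream.
#'
#' @param n number of units.
#' @param rate per-unit rate in Hz (scalar or length-`n` vector).
#' @param dt time step (s).
#' @return logical vector of spike indicators.
#' @export
poisson_spikes <- function(n, rate, dt) {
  if (any(rate < 0)) stop("'rate' must be non-negative")
  stats::runif(n) < rate * dt
}
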