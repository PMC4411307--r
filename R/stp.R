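#' Short-term plasticity state (Tsodyks-Markram)
#'
#' Every excitatory presynaptic neuron carries one pair of short-term
#' plasticity (STP) variables: the utilization `u` (release probability,
#' relaxing towards the baseline `U` with time constant `tau_f`) and the
#' available resources `x` (relaxing towards 1 with time constant `tau_d`).
#' The state is per presynaptic *neuron*, shared by all of its outgoing
#' synapses; the conductance jump caused by a spike of neuron `j` at synapse
#' `(i, j)` is `w_ij * r_j` where `r_j = u_j * x_j` is the release factor.
#'
#' @param n number of presynaptic neurons.
#' @param U baseline utilization (paper value 0.2).
#' @param tau_f facilitation time constant in seconds.
#' @param tau_d depression time constant in seconds.
#' @return object of class `stp_state` with fields `u`, `x` and parameters.
#' @export
stp_state <- function(n, U = 0.2, tau_f = 0.6, tau_d = 0.1) {
  if (U < 0 || U > 1) stop("'U' must lie in [0, 1]")
  if (tau_f <= 0 || tau_d <= 0) stop("STP time constants must be positive")
  structure(list(u = rep(U, n), x = rep(1, n),
                 U = U, tau_f = tau_f, tau_d = tau_d),
            class = "stp_state")
}

#' Advance STP state by one time step
#'
#' Between spikes `u` relaxes exponentially to `U` and `x` to 1.  On a
#' presynaptic spike the utilization is facilitated first,
#' `u <- u + U * (1 - u)`, then the release factor `u * x` is emitted
#' and the resources are depleted, `x <- x - r`.
#'
#' @param state an [stp_state()] object.
#' @param dt time step in seconds.
#' @param pre_spikes `NULL`, logical vector, or integer indices of spiking
#'   presynaptic neurons.
#' @return list with elements `state` (updated) and `release` (numeric vector,
#'   release factor for spiking neurons, 0 elsewhere).
#' @export
step_stp <- function(state, dt, pre_spikes = NULL) {
  stopifnot(inherits(state, "stp_state"))
  if (dt <= 0) stop("'dt' must be positive")
  ef <- exp(-dt / state$tau_f)
  ed <- exp(-dt / state$tau_d)
  state$u <- state$U + (state$u - state$U) * ef
  state$x <- 1 + (state$x - 1) * ed
  release <- numeric(length(state$u))
  if (!is.null(pre_spikes)) {
    if (is.logical(pre_spikes)) pre_spikes <- which(pre_spikes)
    if (length(pre_spikes)) {
      j <- pre_spikes
      state$u[j] <- state$u[j] + state$U * (1 - state$u[j])
      r <- state$u[j] * state$x[j]
      state$x[j] <- state$x[j] - r
      release[j] <- r
    }
  }
  list(state = state, release = release)
}

#' Closed-form STP steady state under periodic presynaptic firing
#'
#' For a presynaptic neuron firing regularly at rate `rate`, the event map of
#' the deterministic Tsodyks-Markram dynamics has the fixed point
#' \deqn{u^- = U / (1 - (1-U) e_f), \quad u^+ = u^- + U (1-u^-),}
#' \deqn{x^- = (1 - e_d) / (1 - (1 - u^+) e_d), \quad r = u^+ x^-,}
#' with \eqn{e_f = e^{-1/(\nu \tau_f)}} and \eqn{e_d = e^{-1/(\nu \tau_d)}}.
#' `u^-`/`x^-` are the values immediately before a spike and `u^+` the
#' facilitated utilization used for release.
#'
#' @param rate presynaptic firing rate in Hz (> 0).
#' @inheritParams stp_state
#' @return list with `u_minus`, `u_plus`, `x_minus` and `release`.
#' @export
stp_steady_state <- function(rate, U = 0.2, tau_f = 0.6, tau_d = 0.1) {
  stopifnot(rate > 0)
  ef <- exp(-1 / (rate * tau_f))
  ed <- exp(-1 / (rate * tau_d))
  u_minus <- U / (1 - (1 - U) * ef)
  u_plus <- u_minus + U * (1 - u_minus)
  x_minus <- (1 - ed) / (1 - (1 - u_plus) * ed)
  list(u_minus = u_minus, u_plus = u_plus, x_minus = x_minus,
       release = u_plus * x_minus)
}
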