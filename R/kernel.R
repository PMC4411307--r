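#' Simulation clock
#'
#' Fixed-step clock used by all simulations.  Neuronal state variables are
#' integrated with forward Euler at `dt` (default 0.1 ms); slow variables
#' (the consolidation reference weights) are updated once every `coarse_dt`,
#' which must be an integer multiple of `dt`.
#'
#' @param dt integration time step in seconds.
#' @param coarse_dt slow-update interval in seconds (default 1.2 s, the
#'   reference-weight update step).
#' @return an object of class `sim_clock` with fields `dt`, `coarse_dt`,
#'   `coarse_steps` (integer ratio) and `t` (current time, starts at 0).
#' @export
sim_clock <- function(dt = 1e-4, coarse_dt = 1.2) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  if (!is.numeric(coarse_dt) || coarse_dt <= 0)
    stop("'coarse_dt' must be a single positive number")
  ratio <- coarse_dt / dt
  if (abs(ratio - round(ratio)) > 1e-6)
    stop("'coarse_dt' must be an integer multiple of 'dt'")
  structure(list(dt = dt, coarse_dt = coarse_dt,
                 coarse_steps = as.integer(round(ratio)), t = 0),
            class = "sim_clock")
}

#' Exponentially decaying spike trace
#'
#' A trace is a per-unit, non-negative activity variable that decays
#' exponentially with time constant `tau` and is incremented by 1 whenever
#' the corresponding unit spikes.  Traces carry all pre- and postsynaptic
#' activity variables of the plasticity rules (fast pre/post traces, the
#' slow postsynaptic trace of the triplet rule, the homeostatic trace, and
#' the traces of the inhibitory rule).
#'
#' @param n number of units.
#' @param tau decay time constant in seconds (> 0).
#' @param value optional initial values (recycled to length `n`).
#' @return an object of class `trace` with fields `value` and `tau`.
#' @export
trace_new <- function(n, tau, value = 0) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  if (any(value < 0)) stop("trace values must be non-negative")
  structure(list(value = rep_len(as.numeric(value), n), tau = tau),
            class = "trace")
}

#' Advance a trace by one time step
#'
#' The trace first decays by the exact exponential factor `exp(-dt/tau)` and
#' is then incremented by 1 for every spiking unit.  Callers that need the
#' "current spike not yet counted" semantics must read the trace *before*
#' calling `step_trace()` for the step in which the spike occurs.
#'
#' @param trace a [trace_new()] object.
#' @param dt time step in seconds (> 0).
#' @param spikes either `NULL` (no spikes), a logical vector of length `n`,
#'   or an integer vector of spiking unit indices.
#' @return the updated trace.
#' @export
step_trace <- function(trace, dt, spikes = NULL) {
  stopifnot(inherits(trace, "trace"))
  if (dt <= 0) stop("'dt' must be positive")
  trace$value <- trace$value * exp(-dt / trace$tau)
  if (!is.null(spikes)) {
    if (is.logical(spikes)) spikes <- which(spikes)
    if (length(spikes)) {
      cnt <- tabulate(spikes, nbins = length(trace$value))
      trace$value <- trace$value + cnt
    }
  }
  trace
}

#' Decay a trace value across an arbitrary interval
#'
#' Convenience for event-driven updates: returns `value * exp(-delta_t/tau)`.
#' @param value trace value(s).
#' @param delta_t elapsed time in seconds (>= 0).
#' @param tau decay time constant in seconds.
#' @return decayed value(s).
#' @export
decay_trace <- function(value, delta_t, tau) {
  if (any(delta_t < 0)) stop("'delta_t' must be non-negative")
  value * exp(-delta_t / tau)
}
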