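#' Parameters of orchestrated excitatory long-term plasticity
#'
#' Excitatory synapses combine four event-triggered mechanisms:
#' \describe{
#'   \item{triplet LTP}{on a postsynaptic spike,
#'     `dw = A * z_plus_j * z_slow_i` (pre trace times *slow* post trace,
#'     both read before the triggering spike is added) -- quadratic in the
#'     postsynaptic rate;}
#'   \item{doublet LTD}{on a presynaptic spike, `dw = -B_i * z_minus_i`
#'     -- linear in the postsynaptic rate;}
#'   \item{heterosynaptic plasticity}{on a postsynaptic spike,
#'     `dw = -beta * (w - wtilde) * z_minus_i^3`; the cubed fast post trace
#'     times the triggering spike gives the fourth-power rate dependence
#'     that acts as a burst detector, pushing `w` towards the reference
#'     weight `wtilde`;}
#'   \item{transmitter-induced plasticity}{on a presynaptic spike,
#'     `dw = +delta`, a small unconditional potentiation.}
#' }
#' Weights are clamped to `[0, w_max]` after every event.  `B_i = A` unless
#' homeostatic metaplasticity of LTD is enabled, in which case `B_i` follows
#' a slow trace of the postsynaptic neuron's own activity (see
#' [update_homeostatic_ltd()]).
#'
#' @param A LTP amplitude (triplet term).
#' @param beta heterosynaptic amplitude; the default is calibrated so the
#'   rate-drift curve has stable zeros near 1 Hz and 30 Hz (see
#'   [calibrate_exc_amplitudes()]).
#' @param delta transmitter-induced amplitude per presynaptic spike.
#' @param B LTD amplitude; `NULL` means `B = A`.
#' @param tau_plus,tau_minus,tau_slow time constants (s) of the fast pre
#'   trace, fast post trace and slow post trace.
#' @param tau_ht time constant (s) of the homeostatic activity trace.
#' @param w_max upper weight bound (paper value 5).
#' @param homeostasis enable homeostatic regulation of LTD.
#' @param theta_ht activity scale (Hz) at which `B_i` saturates at `A`.
#' @param b_min_frac floor of `B_i` as a fraction of `A`.
#' @return object of class `exc_plasticity_params`.
#' @export
exc_plasticity_params <- function(A = 1e-3,
                                  beta = .plastinet_default_beta,
                                  delta = .plastinet_default_delta,
                                  B = NULL,
                                  tau_plus = 20e-3, tau_minus = 20e-3,
                                  tau_slow = .plastinet_default_tau_slow,
                                  tau_ht = 1200,
                                  w_max = 5,
                                  homeostasis = FALSE,
                                  theta_ht = 1, b_min_frac = 0.05) {
  if (A < 0 || beta < 0 || delta < 0) stop("amplitudes must be non-negative")
  if (any(c(tau_plus, tau_minus, tau_slow, tau_ht) <= 0))
    stop("trace time constants must be positive")
  if (w_max <= 0) stop("'w_max' must be positive")
  structure(list(A = A, B = if (is.null(B)) A else B, beta = beta,
                 delta = delta, tau_plus = tau_plus, tau_minus = tau_minus,
                 tau_slow = tau_slow, tau_ht = tau_ht, w_max = w_max,
                 homeostasis = homeostasis, theta_ht = theta_ht,
                 b_min_frac = b_min_frac),
            class = "exc_plasticity_params")
}

#' Presynaptic-spike update of excitatory weights
#'
#' Applies the LTD and transmitter-induced terms triggered by a presynaptic
#' spike: `w <- clamp(w - B * z_minus + delta)`.  `z_minus` must be the fast
#' postsynaptic trace read *before* adding any spike of the current step.
#'
#' @param w weights of the synapses made by the spiking presynaptic neuron.
#' @param z_minus fast postsynaptic trace values of the target neurons.
#' @param params an [exc_plasticity_params()] object.
#' @param B optional per-target LTD amplitudes (defaults to `params$B`).
#' @return list with `w` (updated, clamped) and `n_clamp`.
#' @export
exc_on_pre_spike <- function(w, z_minus, params, B = NULL) {
  if (is.null(B)) B <- params$B
  w_new <- w - B * z_minus + params$delta
  w_cl <- pmin(pmax(w_new, 0), params$w_max)
  list(w = w_cl, n_clamp = sum(w_cl != w_new))
}

#' Postsynaptic-spike update of excitatory weights
#'
#' Applies the triplet LTP and heterosynaptic terms triggered by a
#' postsynaptic spike:
#' `w <- clamp(w + A * z_plus * z_slow - beta * (w - wtilde) * z_minus^3)`.
#' All traces are read before the triggering spike is added.
#'
#' @param w weights of the synapses received by the spiking neuron.
#' @param wtilde matching reference weights.
#' @param z_plus fast presynaptic trace values of the afferent neurons.
#' @param z_slow slow postsynaptic trace value (scalar).
#' @param z_minus fast postsynaptic trace value (scalar).
#' @param params an [exc_plasticity_params()] object.
#' @return list with `w` (updated, clamped) and `n_clamp`.
#' @export
exc_on_post_spike <- function(w, wtilde, z_plus, z_slow, z_minus, params) {
  w_new <- w + params$A * z_plus * z_slow -
    params$beta * (w - wtilde) * z_minus^3
  w_cl <- pmin(pmax(w_new, 0), params$w_max)
  list(w = w_cl, n_clamp = sum(w_cl != w_new))
}

#' Homeostatic regulation of the LTD amplitude
#'
#' When enabled, the LTD amplitude of neuron `i` is a monotone, saturating
#' function of the neuron's own slow activity trace `z_ht` (time constant
#' `tau_ht`, incremented by the neuron's own spikes, so `z_ht / tau_ht`
#' estimates the neuron's long-run rate `nu_hat` in Hz):
#' \deqn{B_i = A \left[ b_{min} + (1 - b_{min})
#'       \min(1,\; \hat\nu_i / \theta_{ht}) \right].}
#' The cap at `A` guarantees that LTD can never remove the elevated-rate
#' fixed point of the drift curve, while a neuron that stays at or below
#' ~1 Hz for a long time sees its LTD amplitude decay towards the floor so
#' that the low-rate plasticity threshold drops and the neuron can start to
#' respond at elevated rates.
#'
#' @param z_ht homeostatic trace value(s) of the postsynaptic neuron(s).
#' @param params an [exc_plasticity_params()] object.
#' @return LTD amplitude(s) `B_i`.
#' @export
update_homeostatic_ltd <- function(z_ht, params) {
  if (!params$homeostasis) return(rep_len(params$A, length(z_ht)))
  nu_hat <- z_ht / params$tau_ht
  params$A * (params$b_min_frac +
                (1 - params$b_min_frac) * pmin(1, nu_hat / params$theta_ht))
}

#' Campbell moments of an exponentially filtered spike train
#'
#' Raw moments (up to third) of a shot-noise trace with unit jumps and decay
#' time constant `tau`, driven by a Poisson train of rate `nu`:
#' cumulants are `k_n = nu * tau / n`, so
#' `E[z] = nu*tau`, `E[z^3] = (nu*tau)^3 + 1.5*(nu*tau)^2 + nu*tau/3`.
#' For a Poisson train these are also the moments seen at the train's own
#' spike times when the trace is read before the current spike is added.
#'
#' @param nu rate in Hz.
#' @param tau trace time constant in seconds.
#' @return list with `m1` and `m3`.
#' @keywords internal
trace_moments <- function(nu, tau) {
  a <- nu * tau
  list(m1 = a, m3 = a^3 + 1.5 * a^2 + a / 3)
}

#' Expected weight drift under independent Poisson firing
#'
#' Analytic expectation of `dw/dt` for a synapse whose pre- and postsynaptic
#' neurons fire as independent Poisson processes at `nu_pre` and `nu_post`:
#' \deqn{\frac{dw}{dt} = A \tau_+ \tau_{slow}\, \nu_{pre} \nu_{post}^2
#'   - B \tau_-\, \nu_{pre} \nu_{post}
#'   - \beta\, d\, \nu_{post}\, E[(z^-)^3]
#'   + \delta\, \nu_{pre},}
#' with `d = w - wtilde`.  With `moments = "exact"` the third moment of the
#' fast post trace uses the full Campbell expansion (this is what a
#' simulation of the event rule converges to); `"schematic"` uses the
#' high-rate approximation `E[(z^-)^3] = (nu_post * tau_-)^3`, which turns
#' the heterosynaptic term into the schematic quartic
#' `beta * d * tau_-^3 * nu_post^4`.
#'
#' When the postsynaptic spike train is not Poisson (for example the
#' partially regular train of a conductance-based neuron in the mean-driven
#' regime), the moments of its own traces at its own spike times deviate
#' from the Campbell values; `kappa_slow` and `kappa3` are multiplicative
#' correction factors for `E[z_slow]` and `E[(z^-)^3]` at spike times
#' (1 = Poisson).  They can be measured with [trace_values_at_spikes()].
#'
#' @param params an [exc_plasticity_params()] object.
#' @param nu_pre presynaptic rate in Hz.
#' @param nu_post postsynaptic rate(s) in Hz (vectorised).
#' @param d operating value of `w - wtilde` entering the heterosynaptic term.
#' @param moments `"exact"` or `"schematic"`.
#' @param B LTD amplitude override (defaults to `params$B`).
#' @param kappa_slow,kappa3 moment-correction factors for non-Poisson
#'   postsynaptic trains (see Details).
#' @return expected `dw/dt` (weight units per second), same length as
#'   `nu_post`.
#' @export
rate_drift_curve <- function(params, nu_pre, nu_post, d = 0.2,
                             moments = c("exact", "schematic"), B = NULL,
                             kappa_slow = 1, kappa3 = 1) {
  moments <- match.arg(moments)
  if (is.null(B)) B <- params$B
  ltp <- params$A * params$tau_plus * params$tau_slow * nu_pre * nu_post^2 *
    kappa_slow
  ltd <- B * params$tau_minus * nu_pre * nu_post
  m3 <- if (moments == "exact") {
    trace_moments(nu_post, params$tau_minus)$m3
  } else {
    (nu_post * params$tau_minus)^3
  }
  het <- params$beta * d * nu_post * m3 * kappa3
  ti <- params$delta * nu_pre
  ltp - ltd - het + ti
}

#' Calibrate the non-Hebbian amplitudes from the target fixed points
#'
#' Given the triplet amplitude `A`, solves for the transmitter-induced
#' amplitude `delta` and the heterosynaptic amplitude `beta` such that the
#' rate-drift curve vanishes at the two target postsynaptic rates (the
#' published stable fixed points sit near 1 Hz and 30 Hz) for presynaptic
#' rate `nu_pre` and operating weight offsets `d_op`.  The system is linear
#' in `(delta, beta)` and solved exactly.
#'
#' @param A triplet LTP amplitude.
#' @param nu_pre presynaptic rate in Hz (10 Hz in the feed-forward setup).
#' @param targets length-2 vector of target zero-crossing rates (Hz).
#' @param d_op operating values of `w - wtilde` at the two targets
#'   (recycled to length 2).
#' @param tau_plus,tau_minus,tau_slow trace time constants (s).
#' @param moments moment approximation passed to the drift curve.
#' @return list with `delta`, `beta`, and the solved `params` object.
#' @export
calibrate_exc_amplitudes <- function(A = 1e-3, nu_pre = 10,
                                     targets = c(1, 30),
                                     d_op = c(0.12, 0.2),
                                     tau_plus = 20e-3, tau_minus = 20e-3,
                                     tau_slow = .plastinet_default_tau_slow,
                                     moments = "exact") {
  stopifnot(length(targets) == 2L, all(targets > 0))
  d_op <- rep_len(d_op, 2L)
  m3 <- function(nu) {
    if (moments == "exact") trace_moments(nu, tau_minus)$m3
    else (nu * tau_minus)^3
  }
  ## nu_pre * delta - d_k * nu_k * m3(nu_k) * beta = -(ltp_k - ltd_k)
  ltp <- A * tau_plus * tau_slow * nu_pre * targets^2
  ltd <- A * tau_minus * nu_pre * targets
  M <- rbind(c(nu_pre, -d_op[1] * targets[1] * m3(targets[1])),
             c(nu_pre, -d_op[2] * targets[2] * m3(targets[2])))
  sol <- solve(M, -(ltp - ltd))
  if (any(sol <= 0))
    stop("calibration produced non-positive amplitudes; adjust targets/d_op")
  params <- exc_plasticity_params(A = A, beta = sol[2], delta = sol[1],
                                  tau_plus = tau_plus, tau_minus = tau_minus,
                                  tau_slow = tau_slow)
  list(delta = sol[1], beta = sol[2], params = params)
}

#' Stable zero-crossings of the rate-drift curve
#'
#' Finds downward zero-crossings (stable fixed points of the postsynaptic
#' rate in the drift sense) of [rate_drift_curve()] on a rate grid.
#'
#' @inheritParams rate_drift_curve
#' @param grid postsynaptic rate grid (Hz).
#' @return numeric vector of downward crossing rates (Hz).
#' @export
drift_fixed_points <- function(params, nu_pre = 10, d = 0.2,
                               grid = seq(0.01, 100, by = 0.01),
                               moments = "exact", ...) {
  g <- rate_drift_curve(params, nu_pre, grid, d = d, moments = moments, ...)
  s <- sign(g)
  idx <- which(s[-length(s)] > 0 & s[-1] <= 0)
  vapply(idx, function(i) {
    stats::uniroot(function(nu)
      rate_drift_curve(params, nu_pre, nu, d = d, moments = moments, ...),
      lower = grid[i], upper = grid[i + 1])$root
  }, numeric(1))
}
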