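#' Trace values at the spike times of a train
#'
#' Returns the value of an exponentially decaying unit-jump trace of the
#' train itself, read at each spike time *before* that spike is added (the
#' plasticity convention).  Used to measure the moment-correction factors
#' of non-Poisson trains.
#'
#' @param spike_times sorted numeric vector of spike times (s).
#' @param tau trace time constant (s).
#' @return numeric vector, same length as `spike_times`.
#' @export
trace_values_at_spikes <- function(spike_times, tau) {
  z <- 0
  out <- numeric(length(spike_times))
  for (k in seq_along(spike_times)) {
    if (k > 1) z <- (z + 1) * exp(-(spike_times[k] - spike_times[k - 1]) / tau)
    out[k] <- z
  }
  out
}

#' Full fixed-point calibration of the orchestrated plasticity amplitudes
#'
#' Reproduces the calibration that produced the package defaults.  With the
#' triplet amplitude `A` fixed, the transmitter-induced amplitude `delta`
#' and the heterosynaptic amplitude `beta` are solved such that the weight
#' drift vanishes at the two target postsynaptic rates (the published
#' stable fixed points near 1 Hz and 30 Hz) *for the actual neuron model*:
#' \enumerate{
#'   \item static-weight simulations of the feed-forward setup (`n_syn`
#'     Poisson inputs at `nu_pre` plus a 1-Hz control pathway) locate the
#'     weights at which the output rate matches each target;
#'   \item the trace-moment correction factors `kappa_slow` (for the slow
#'     post trace in the LTP term) and `kappa3` (for the cubed fast post
#'     trace in the heterosynaptic term) are measured from the recorded
#'     spike trains, because the conductance-based neuron does not fire as
#'     a Poisson process;
#'   \item the operating value of `w - wtilde` at the elevated fixed point
#'     is taken from the equilibrium of the consolidation dynamics at the
#'     located weight;
#'   \item `delta` is solved from the low-rate balance (where the
#'     heterosynaptic term is negligible) and `beta` from the high-rate
#'     balance.
#' }
#'
#' @param np a [neuron_params()] object.
#' @param A triplet LTP amplitude (fixed).
#' @param nu_pre active-pathway rate in Hz.
#' @param n_syn number of active-pathway synapses.
#' @param targets the two target rates (Hz).
#' @param w_grid weight grid bracketing the two targets for the static-rate
#'   search.
#' @param tau_plus,tau_minus,tau_slow trace time constants (s).
#' @param cons a [consolidation_params()] object.
#' @param duration duration (s) of each static calibration run.
#' @param seed RNG seed for the calibration runs.
#' @return list with `delta`, `beta`, `w_high`, `w_low`, `d_op`,
#'   `kappa_slow`, `kappa3`, `kappa_slow_low` and a ready-made `params`
#'   object.
#' @export
calibrate_orchestration <- function(np = neuron_params(), A = 1e-3,
                                    nu_pre = 10, n_syn = 80,
                                    targets = c(1, 30),
                                    w_grid = c(0.15, 2),
                                    tau_plus = 20e-3, tau_minus = 20e-3,
                                    tau_slow = .plastinet_default_tau_slow,
                                    cons = consolidation_params(),
                                    duration = 200, seed = 11) {
  discard <- min(20, duration / 4)
  static_rate <- function(w0) {
    post <- pop_lif(1, np, record_spikes = TRUE)
    act <- pop_poisson(n_syn, rate = nu_pre)
    ctl <- pop_poisson(n_syn, rate = 1)
    c1 <- connection(2, 1, seq_len(n_syn) - 1, rep(0, n_syn), w0,
                     "static_exc")
    c2 <- connection(3, 1, seq_len(n_syn) - 1, rep(0, n_syn), 0.1,
                     "static_exc")
    r <- simulate_network(list(post, act, ctl), list(c1, c2), duration,
                          seed = seed, rate_bin = duration)
    st <- r$spikes[[1]]$time
    st[st > discard]
  }
  find_w <- function(target) {
    stats::uniroot(function(w) {
      length(static_rate(w)) / (duration - discard) - target
    }, interval = w_grid, tol = 0.01)$root
  }
  w_low <- find_w(targets[1])
  w_high <- find_w(targets[2])
  st_hi <- static_rate(w_high)
  nu_hi <- length(st_hi) / (duration - discard)
  st_lo <- static_rate(w_low)
  nu_lo <- length(st_lo) / (duration - discard)
  m3p <- function(nu) trace_moments(nu, tau_minus)$m3
  kappa_slow <- mean(trace_values_at_spikes(st_hi, tau_slow)) /
    (nu_hi * tau_slow)
  kappa3 <- mean(trace_values_at_spikes(st_hi, tau_minus)^3) / m3p(nu_hi)
  kappa_slow_low <- mean(trace_values_at_spikes(st_lo, tau_slow)) /
    (nu_lo * tau_slow)
  ## operating w - wtilde: consolidation equilibrium at the high weight
  wt_eq <- stats::uniroot(function(wt)
    (w_high - wt) - cons$P * wt * (cons$w_P / 2 - wt) * (cons$w_P - wt),
    interval = c(cons$w_P, 10 * cons$w_P))$root
  d_op <- w_high - wt_eq
  nu1 <- targets[1]; nu2 <- targets[2]
  delta <- (A * tau_minus * nu_pre * nu1 -
              A * tau_plus * tau_slow * nu_pre * nu1^2 * kappa_slow_low) /
    nu_pre
  beta <- (A * tau_plus * tau_slow * nu_pre * nu2^2 * kappa_slow -
             A * tau_minus * nu_pre * nu2 + delta * nu_pre) /
    (d_op * nu2 * kappa3 * m3p(nu2))
  if (beta <= 0 || delta <= 0)
    stop("calibration produced non-positive amplitudes")
  params <- exc_plasticity_params(A = A, beta = beta, delta = delta,
                                  tau_plus = tau_plus,
                                  tau_minus = tau_minus,
                                  tau_slow = tau_slow)
  list(delta = delta, beta = beta, w_high = w_high, w_low = w_low,
       d_op = d_op, kappa_slow = kappa_slow, kappa3 = kappa3,
       kappa_slow_low = kappa_slow_low, params = params)
}
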