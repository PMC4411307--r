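#' Population constructors for the network engine
#'
#' `pop_lif()` creates a conductance-based integrate-and-fire population,
#' `pop_poisson()` a Poisson input population with optional stimulus
#' modulation, and `pop_spike_source()` a population emitting a prescribed
#' list of spikes (useful for fully deterministic probes).
#'
#' @param n number of units.
#' @param params a [neuron_params()] object (LIF populations).
#' @param rate baseline per-unit rate in Hz, scalar or length-`n`.
#' @param stimulus `NULL` or a list with elements `zeta` (matrix `n` x
#'   `n_patterns` of activation values in `[0,1]`), `schedule` (data.frame
#'   with columns `pattern` (1-based), `t_start`, `t_end` in seconds) and
#'   `increment` (rate increment in Hz at `zeta = 1`; default 35).
#' @param times,ids spike times (s) and 0-based unit ids for a spike source.
#' @param record_spikes record this population's raster.
#' @return a population description list.
#' @name populations
NULL

#' @rdname populations
#' @export
pop_lif <- function(n, params = neuron_params(), record_spikes = TRUE) {
  stopifnot(inherits(params, "neuron_params"))
  list(type = "lif", n = as.integer(n), params = unclass(params),
       record_spikes = record_spikes)
}

#' @rdname populations
#' @export
pop_poisson <- function(n, rate = 10, stimulus = NULL,
                        record_spikes = FALSE) {
  if (any(rate < 0)) stop("'rate' must be non-negative")
  if (!is.null(stimulus)) {
    sch <- stimulus$schedule
    stopifnot(is.matrix(stimulus$zeta), nrow(stimulus$zeta) == n,
              all(c("pattern", "t_start", "t_end") %in% names(sch)))
    stimulus <- list(zeta = stimulus$zeta,
                     pattern = as.integer(sch$pattern),
                     t0 = as.numeric(sch$t_start),
                     t1 = as.numeric(sch$t_end),
                     increment = if (is.null(stimulus$increment)) 35
                                 else stimulus$increment)
  }
  list(type = "poisson", n = as.integer(n), rate = as.numeric(rate),
       stimulus = stimulus, record_spikes = record_spikes)
}

#' @rdname populations
#' @export
pop_spike_source <- function(n, times, ids, record_spikes = FALSE) {
  stopifnot(length(times) == length(ids), all(ids >= 0), all(ids < n))
  list(type = "spike_source", n = as.integer(n),
       times = as.numeric(times), ids = as.integer(ids),
       record_spikes = record_spikes)
}

#' Connection constructor for the network engine
#'
#' Describes one synapse population between two registered populations.
#' `pre`/`post` are 0-based unit indices into the source and target
#' populations; `w` the initial weights.
#'
#' @param src,dst 1-based indices of the source and target populations in
#'   the population list passed to [simulate_network()].
#' @param pre,post 0-based presynaptic/postsynaptic unit indices.
#' @param w initial weights (scalar or per-synapse).
#' @param type one of `"static_exc"`, `"static_inh"`, `"plastic_exc"`,
#'   `"plastic_inh"`.
#' @param stp apply short-term plasticity scaling (default: all excitatory
#'   connections; never applied to inhibitory ones).
#' @param params an [exc_plasticity_params()] or [inh_plasticity_params()]
#'   object for plastic connections.
#' @param wtilde initial reference weights (plastic excitatory; default `w`).
#' @param consolidation `NULL` (reference weights frozen) or a
#'   [consolidation_params()] object, optionally with a `freeze_t` element
#'   (time in s after which the reference weights are frozen).
#' @param plasticity_start time (s) before which plasticity updates are
#'   skipped (traces still accumulate).
#' @param record_w_every interval (s) for recording mean weight, mean
#'   reference weight and clamp counts (0 = off).
#' @param record_syn 1-based synapse indices whose weights are recorded at
#'   the same interval.
#' @return a connection description list.
#' @export
connection <- function(src, dst, pre, post, w,
                       type = c("static_exc", "static_inh",
                                "plastic_exc", "plastic_inh"),
                       stp = NULL, params = NULL, wtilde = NULL,
                       consolidation = NULL, plasticity_start = 0,
                       record_w_every = 0, record_syn = NULL) {
  type <- match.arg(type)
  n_syn <- length(pre)
  stopifnot(length(post) == n_syn)
  w <- rep_len(as.numeric(w), n_syn)
  if (is.null(stp)) stp <- type %in% c("static_exc", "plastic_exc")
  if (type == "plastic_exc") {
    if (is.null(params)) params <- exc_plasticity_params()
    stopifnot(inherits(params, "exc_plasticity_params"))
  } else if (type == "plastic_inh") {
    if (is.null(params)) params <- inh_plasticity_params()
    stopifnot(inherits(params, "inh_plasticity_params"))
  }
  cons <- NULL
  if (!is.null(consolidation)) {
    stopifnot(inherits(consolidation, "consolidation_params"))
    cons <- list(enabled = TRUE, P = consolidation$P,
                 w_P = consolidation$w_P, tau_cons = consolidation$tau_cons,
                 freeze_t = if (is.null(consolidation$freeze_t)) -1
                            else consolidation$freeze_t)
  }
  list(src = as.integer(src), dst = as.integer(dst),
       pre = as.integer(pre), post = as.integer(post), w = w,
       type = type, stp = stp,
       params = if (is.null(params)) NULL else unclass(params),
       wtilde = if (is.null(wtilde)) NULL else rep_len(as.numeric(wtilde), n_syn),
       consolidation = cons,
       plasticity_start = plasticity_start,
       record_w_every = record_w_every,
       record_syn = if (is.null(record_syn)) NULL else as.integer(record_syn))
}

#' Run a clock-driven network simulation
#'
#' Integrates the registered populations and connections for `duration`
#' seconds with forward Euler at `dt`.  All randomness is drawn from
#' counter-based streams derived from `seed` (one stream per population), so
#' identical configurations and seeds produce bit-identical spike output.
#'
#' @param populations list of population descriptions ([pop_lif()],
#'   [pop_poisson()], [pop_spike_source()]).
#' @param connections list of [connection()] descriptions.
#' @param duration simulated time in seconds.
#' @param dt integration step in seconds (default 0.1 ms).
#' @param seed integer root seed.
#' @param delay conduction delay in seconds, identical for all connections
#'   (default 0.8 ms).
#' @param coarse_dt slow-update interval (s) for the reference weights.
#' @param stp_params list with `U`, `tau_f`, `tau_d` (applies to all
#'   connections with `stp = TRUE`; one state per presynaptic neuron).
#' @param rate_bin bin width (s) of the returned population-rate series.
#' @return list with components `spikes` (per population: data.frame
#'   `time`, `id`), `connections` (per connection: final `w`, `wtilde`,
#'   clamp count, optional recorded series), `rates` (matrix bins x
#'   populations) and `rate_times`.
#' @export
simulate_network <- function(populations, connections, duration,
                             dt = 1e-4, seed = 1, delay = 8e-4,
                             coarse_dt = 1.2,
                             stp_params = list(U = 0.2, tau_f = 0.6,
                                               tau_d = 0.1),
                             rate_bin = 0.5) {
  stopifnot(duration > 0, dt > 0, length(populations) >= 1)
  for (cn in connections) {
    if (cn$src > length(populations) || cn$dst > length(populations))
      stop("connection endpoints not registered")
    np_src <- populations[[cn$src]]$n; np_dst <- populations[[cn$dst]]$n
    if (length(cn$pre) && (max(cn$pre) >= np_src || max(cn$post) >= np_dst))
      stop("synapse indices out of range")
  }
  cfg <- list(dt = dt, duration = duration, seed = as.numeric(seed),
              delay = delay, coarse_dt = coarse_dt, stp = stp_params,
              rate_bin = rate_bin,
              populations = populations, connections = connections)
  res <- cpp_simulate(cfg)
  res$spikes <- lapply(res$spikes, function(s)
    data.frame(time = s$time, id = s$id))
  res
}
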