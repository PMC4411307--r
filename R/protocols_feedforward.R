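.protocol_result <- function(protocol, seed, config, summary,
                             rasters = NULL, weights = NULL,
                             series = NULL) {
  structure(list(protocol = protocol, seed = seed, config = config,
                 summary = summary, rasters = rasters, weights = weights,
                 series = series),
            class = "protocol_result")
}

#' Single-neuron feed-forward bistability experiment
#'
#' One conductance-based integrate-and-fire neuron receives 80 plastic
#' excitatory synapses from Poisson neurons firing at 10 Hz (active
#' pathway, initial weight `initial_w`) and 80 from a control pathway at
#' 1 Hz (initial weight 0.1).  All orchestrated excitatory plasticity
#' mechanisms and the consolidation dynamics are active; plasticity is
#' switched on after 60 s of burn-in.  Depending on which side of the
#' separatrix `initial_w` lies (between 0.2 and 0.35), the output rate
#' converges to the low (~1 Hz) or elevated (~30 Hz) stable fixed point.
#'
#' @param initial_w initial weight of the active pathway.
#' @param duration simulated time (s); at least 600 s for convergence.
#' @param seed RNG seed.
#' @param np,pp,cons neuron, plasticity and consolidation parameters.
#' @param n_syn synapses per pathway.
#' @param plasticity_start burn-in before plasticity is enabled (s).
#' @param measure_window length (s) of the final window over which the
#'   converged output rate is averaged.
#' @return `protocol_result`; `summary` holds `rate` (converged output
#'   rate, Hz), `max_w`, `clamp_events_after_burnin`, final weights and
#'   reference weights per pathway.
#' @export
run_single_neuron_bistability <- function(initial_w = 0.35, duration = 600,
                                          seed = 1,
                                          np = neuron_params(),
                                          pp = exc_plasticity_params(),
                                          cons = consolidation_params(),
                                          n_syn = 80,
                                          plasticity_start = 60,
                                          measure_window = 120) {
  post <- pop_lif(1, np, record_spikes = TRUE)
  act <- pop_poisson(n_syn, rate = 10)
  ctl <- pop_poisson(n_syn, rate = 1)
  idx <- seq_len(n_syn) - 1L
  c_act <- connection(2, 1, idx, rep(0L, n_syn), initial_w, "plastic_exc",
                      params = pp, consolidation = cons,
                      plasticity_start = plasticity_start,
                      record_w_every = 10)
  c_ctl <- connection(3, 1, idx, rep(0L, n_syn), 0.1, "plastic_exc",
                      params = pp, consolidation = cons,
                      plasticity_start = plasticity_start,
                      record_w_every = 10)
  res <- simulate_network(list(post, act, ctl), list(c_act, c_ctl),
                          duration = duration, seed = seed, rate_bin = 10)
  st <- res$spikes[[1]]$time
  rate <- sum(st >= duration - measure_window) / measure_window
  ser <- res$connections[[1]]$series
  after <- ser$t > plasticity_start + 60  # transient after enabling
  clamps <- sum(ser$clamps[after]) +
    sum(res$connections[[2]]$series$clamps[after])
  summary <- list(
    initial_w = initial_w, rate = rate,
    max_w = max(res$connections[[1]]$w, res$connections[[2]]$w),
    w_max_bound = pp$w_max,
    clamp_events_after_burnin = clamps,
    mean_w_active = mean(res$connections[[1]]$w),
    mean_wtilde_active = mean(res$connections[[1]]$wtilde),
    mean_w_control = mean(res$connections[[2]]$w))
  .protocol_result("single_neuron_bistability", seed,
                   list(initial_w = initial_w, duration = duration,
                        n_syn = n_syn, np = unclass(np), pp = unclass(pp)),
                   summary,
                   rasters = list(post = res$spikes[[1]]),
                   weights = list(active = list(
                     pre = res$connections[[1]]$pre,
                     post = res$connections[[1]]$post,
                     w = res$connections[[1]]$w,
                     wtilde = res$connections[[1]]$wtilde,
                     n_pre = n_syn, n_post = 1, class = "input_e")),
                   series = list(rate_times = res$rate_times,
                                 rates = res$rates,
                                 w_active = ser,
                                 w_control = res$connections[[2]]$series))
}

#' Receptive-field development under shifting localized stimulation
#'
#' A single neuron with `n_inputs` plastic Poisson inputs (initial weight
#' `w0`) at a 10-Hz background rate.  From `t = 100 s` on, a Gaussian
#' activation profile (s.d. `sigma` in input-index units) modulates the
#' input rates; the profile centre is re-drawn at random intervals
#' (`T_on = 20 s` mean hold, `T_off = 100 ms`).  Synaptic competition
#' localizes the weight vector into a single dominant bump.
#'
#' @param n_inputs number of input synapses.
#' @param duration simulated time (s).
#' @param sigma profile width (index units).
#' @param w0 initial weight.
#' @param seed RNG seed.
#' @param np,pp,cons model parameters.
#' @return `protocol_result`; `summary` holds the localization score
#'   (largest fraction of total weight mass inside a sliding window of
#'   width `4 * sigma`), its centre, and the final weight vector is in
#'   `weights`.
#' @export
run_receptive_field_formation <- function(n_inputs = 1000, duration = 1200,
                                          sigma = 50, w0 = 0.05, seed = 1,
                                          np = neuron_params(),
                                          pp = exc_plasticity_params(),
                                          cons = consolidation_params()) {
  zeta <- make_gaussian_profile_stimuli(n_inputs, sigma, 10, seed = seed)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed + 1)
  sch <- schedule_stimuli(duration, ncol(zeta), T_on = 20, T_off = 0.1,
                          burn_in = 100)
  post <- pop_lif(1, np, record_spikes = TRUE)
  inp <- pop_poisson(n_inputs, rate = 10,
                     stimulus = list(zeta = zeta, schedule = sch,
                                     increment = 35))
  cn <- connection(2, 1, seq_len(n_inputs) - 1L, rep(0L, n_inputs), w0,
                   "plastic_exc", params = pp, consolidation = cons,
                   record_w_every = 20)
  res <- simulate_network(list(post, inp), list(cn), duration = duration,
                          seed = seed, rate_bin = 10)
  w <- res$connections[[1]]$w
  win <- round(4 * sigma)
  cs <- cumsum(w)
  frac <- vapply(seq_len(n_inputs - win), function(i)
    (cs[i + win] - cs[i]) / cs[n_inputs], numeric(1))
  summary <- list(localization = max(frac),
                  bump_centre = which.max(frac) + win / 2,
                  window = win, mean_w = mean(w))
  .protocol_result("receptive_field_formation", seed,
                   list(n_inputs = n_inputs, duration = duration,
                        sigma = sigma, w0 = w0),
                   summary,
                   rasters = list(post = res$spikes[[1]]),
                   weights = list(input = list(
                     pre = res$connections[[1]]$pre,
                     post = res$connections[[1]]$post,
                     w = w, wtilde = res$connections[[1]]$wtilde,
                     n_pre = n_inputs, n_post = 1, class = "input_e")),
                   series = res$connections[[1]]$series)
}

#' Postsynaptic tetanization protocol
#'
#' Event-driven simulation of 1000 plastic synapses onto one neuron whose
#' weights and reference weights are drawn independently from
#' Normal(0.3, 0.3) truncated at zero.  Two pathways of 500 synapses are
#' probed alternatingly with one spike each (50 ms apart) every 7.5 s,
#' except during the tetanus (minute 10 to 13) in which the postsynaptic
#' neuron is forced to fire three spike-trains with 1-min offsets, each
#' consisting of 10 bursts at 1 Hz with five spikes at 100 Hz.  Depending
#' on its initial state a synapse shows LTP (`w < wtilde`), LTD
#' (`w > wtilde`) or no change (`w = wtilde`).
#'
#' @param seed RNG seed for the initial weight draw.
#' @param pp,cons plasticity and consolidation parameters.
#' @param duration total protocol time (s), tetanus at minute 10-13.
#' @return `protocol_result`; `summary` holds the Pearson correlation of
#'   the tetanus-induced weight change with `w - wtilde`, group means, and
#'   per-synapse columns in `summary$synapses`.
#' @export
run_tetanization <- function(seed = 1, pp = exc_plasticity_params(),
                             cons = consolidation_params(),
                             duration = 1200) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- 1000
  w <- pmax(stats::rnorm(n, 0.3, 0.3), 0)
  wt <- pmax(stats::rnorm(n, 0.3, 0.3), 0)
  pathway <- rep(1:2, each = n / 2)

  t_tet <- 600                       # tetanus onset (minute 10)
  t_tet_end <- 780
  ## probe times: pathway 1 at k*7.5, pathway 2 50 ms later (paused
  ## during tetanization)
  probe1 <- seq(7.5, duration - 1, by = 7.5)
  probe1 <- probe1[probe1 < t_tet | probe1 > t_tet_end]
  probe2 <- probe1 + 0.05
  ## post spikes: 3 trains (1-min offsets), 10 bursts at 1 Hz,
  ## 5 spikes at 100 Hz
  burst <- seq(0, by = 0.01, length.out = 5)
  train <- as.vector(outer(burst, seq(0, by = 1, length.out = 10), "+"))
  post_times <- as.vector(outer(train, t_tet + c(0, 60, 120), "+"))

  ev_t <- c(probe1, probe2, post_times)
  ev_type <- rep(c(1L, 2L, 3L),
                 c(length(probe1), length(probe2), length(post_times)))
  o <- order(ev_t, ev_type)
  ev_t <- ev_t[o]; ev_type <- ev_type[o]

  zp <- c(0, 0); zm <- 0; zs <- 0
  t_last <- 0
  cons_t <- seq(cons$interval, duration, by = cons$interval)
  ci <- 1L
  w_pre_tet <- NULL; wt_pre_tet <- NULL
  for (k in seq_along(ev_t)) {
    t <- ev_t[k]
    while (ci <= length(cons_t) && cons_t[ci] <= t) {
      wt <- step_reference_weights(w, wt, cons)
      ci <- ci + 1L
    }
    dt_ev <- t - t_last
    zp <- decay_trace(zp, dt_ev, pp$tau_plus)
    zm <- decay_trace(zm, dt_ev, pp$tau_minus)
    zs <- decay_trace(zs, dt_ev, pp$tau_slow)
    t_last <- t
    if (is.null(w_pre_tet) && t >= t_tet) { w_pre_tet <- w; wt_pre_tet <- wt }
    if (ev_type[k] <= 2L) {           # probe spike of one pathway
      sel <- pathway == ev_type[k]
      w[sel] <- pmin(pmax(w[sel] - pp$B * zm + pp$delta, 0), pp$w_max)
      zp[ev_type[k]] <- zp[ev_type[k]] + 1
    } else {                          # postsynaptic tetanus spike
      w <- pmin(pmax(w + pp$A * zp[pathway] * zs -
                       pp$beta * (w - wt) * zm^3, 0), pp$w_max)
      zm <- zm + 1; zs <- zs + 1
    }
  }
  if (is.null(w_pre_tet)) { w_pre_tet <- w; wt_pre_tet <- wt }
  dw <- w - w_pre_tet
  d0 <- w_pre_tet - wt_pre_tet
  grp <- cut(d0, c(-Inf, -0.01, 0.01, Inf),
             labels = c("w<wt", "w~wt", "w>wt"))
  summary <- list(
    correlation = stats::cor(dw, d0),
    mean_dw_w_gt_wt = mean(dw[grp == "w>wt"]),
    mean_dw_w_lt_wt = mean(dw[grp == "w<wt"]),
    mean_abs_rel_change_w_eq_wt =
      mean(abs(dw[grp == "w~wt"]) / pmax(w_pre_tet[grp == "w~wt"], 0.05)),
    synapses = data.frame(w0 = w_pre_tet, wtilde0 = wt, dw = dw, d0 = d0))
  .protocol_result("tetanization", seed,
                   list(duration = duration, pp = unclass(pp)), summary)
}

#' STDP pairing-frequency curves
#'
#' Classical pairing protocol: `n_pairs` pre/post spike pairs at fixed
#' timing `dt_pair` (+10 ms pre-before-post or -10 ms post-before-pre) and
#' varying pairing frequency, for the full orchestrated rule and for the
#' pure triplet rule (`beta = delta = 0`).  Below 40 Hz the orchestrated
#' rule reproduces the triplet frequency dependence; at high frequencies
#' heterosynaptic braking reduces potentiation.
#'
#' @param frequencies pairing frequencies in Hz.
#' @param dt_pair pairing offsets in seconds.
#' @param n_pairs number of pairings (reference protocol: 75).
#' @param w0 initial weight (= initial reference weight).
#' @param pp plasticity parameters for the orchestrated rule.
#' @return data.frame with columns `freq`, `dt`, `dw_orchestrated`,
#'   `dw_triplet`.
#' @export
run_pairing_curves <- function(frequencies = c(1, 5, 10, 20, 40, 50),
                               dt_pair = c(0.01, -0.01), n_pairs = 75,
                               w0 = 0.5, pp = exc_plasticity_params()) {
  pp_trip <- exc_plasticity_params(A = pp$A, beta = 0, delta = 0,
                                   tau_plus = pp$tau_plus,
                                   tau_minus = pp$tau_minus,
                                   tau_slow = pp$tau_slow,
                                   w_max = pp$w_max)
  out <- expand.grid(freq = frequencies, dt = dt_pair)
  out$dw_orchestrated <- NA_real_
  out$dw_triplet <- NA_real_
  for (r in seq_len(nrow(out))) {
    base <- seq(0, by = 1 / out$freq[r], length.out = n_pairs)
    if (out$dt[r] >= 0) { pre <- base; post <- base + out$dt[r] }
    else { post <- base; pre <- base - out$dt[r] }
    ro <- run_synapse_protocol(pre, post, pp, w0 = w0, wtilde0 = w0)
    rt <- run_synapse_protocol(pre, post, pp_trip, w0 = w0, wtilde0 = w0)
    out$dw_orchestrated[r] <- ro$w - w0
    out$dw_triplet[r] <- rt$w - w0
  }
  out
}
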