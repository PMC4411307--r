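#' Event-driven simulation of a single plastic excitatory synapse
#'
#' Exact event-driven integration of the orchestrated plasticity rule for
#' one synapse with prescribed pre- and postsynaptic spike times.  Traces
#' decay exactly between events and are read *before* the triggering spike
#' is added.  All events sharing one timestamp read the traces as of
#' before that timestamp (weight updates ordered pre-first) and their
#' trace increments are applied afterwards, matching the network engine's
#' within-step convention; simultaneous events must carry exactly equal
#' time values.  Used by the induction protocols (pairing curves,
#' tetanization) and by the Monte-Carlo drift oracle.
#'
#' @param pre_times,post_times numeric vectors of spike times in seconds
#'   (need not be sorted).
#' @param params an [exc_plasticity_params()] object.
#' @param w0 initial weight.
#' @param wtilde0 initial reference weight (defaults to `w0`).
#' @param consolidation `NULL` (reference weight frozen) or a
#'   [consolidation_params()] object; when given, `wtilde` is updated on the
#'   `interval` grid.
#' @param t_end end of the simulated interval (defaults to the last spike).
#' @param freeze_w if `TRUE`, weight updates are accumulated in `dw` but the
#'   weight entering the heterosynaptic term stays at `w0` (measurement mode
#'   for drift estimation at a fixed operating point `w0 - wtilde0`).
#' @param record if `TRUE`, return the weight trajectory at every event.
#' @return list with `w`, `wtilde`, `dw` (total accumulated change),
#'   `n_clamp`, and optionally `trajectory` (data.frame `t`, `w`, `wtilde`).
#' @export
run_synapse_protocol <- function(pre_times, post_times, params,
                                 w0 = 0.5, wtilde0 = w0,
                                 consolidation = NULL, t_end = NULL,
                                 freeze_w = FALSE, record = FALSE) {
  ev_t <- c(pre_times, post_times)
  ev_type <- rep(c(1L, 2L), c(length(pre_times), length(post_times)))
  o <- order(ev_t, ev_type)
  ev_t <- ev_t[o]; ev_type <- ev_type[o]
  if (is.null(t_end)) t_end <- if (length(ev_t)) max(ev_t) else 0

  cons_t <- if (!is.null(consolidation)) {
    seq(consolidation$interval, t_end, by = consolidation$interval)
  } else numeric(0)

  w <- w0; wt <- wtilde0; dw <- 0; n_clamp <- 0L
  zp <- 0; zm <- 0; zs <- 0; zht <- 0
  t_last <- 0
  ci <- 1L
  traj_t <- traj_w <- traj_wt <- numeric(0)

  clamp <- function(x) min(max(x, 0), params$w_max)

  apply_dw <- function(delta_w) {
    if (freeze_w) {
      dw <<- dw + delta_w
    } else {
      w_new <- w + delta_w
      w_cl <- clamp(w_new)
      if (w_cl != w_new) n_clamp <<- n_clamp + 1L
      dw <<- dw + (w_cl - w)
      w <<- w_cl
    }
  }

  advance_cons <- function(t) {
    while (ci <= length(cons_t) && cons_t[ci] <= t) {
      wt <<- step_reference_weights(if (freeze_w) w0 else w, wt,
                                    consolidation)
      ci <<- ci + 1L
    }
  }

  k <- 1L
  n_ev <- length(ev_t)
  while (k <= n_ev) {
    t <- ev_t[k]
    advance_cons(t)
    dt_ev <- t - t_last
    zp <- decay_trace(zp, dt_ev, params$tau_plus)
    zm <- decay_trace(zm, dt_ev, params$tau_minus)
    zs <- decay_trace(zs, dt_ev, params$tau_slow)
    zht <- decay_trace(zht, dt_ev, params$tau_ht)
    t_last <- t
    ## all events sharing this timestamp read the traces as of before the
    ## timestamp ("current spikes not yet counted"); increments follow
    n_pre_here <- 0L; n_post_here <- 0L
    while (k <= n_ev && ev_t[k] == t) {
      if (ev_type[k] == 1L) {        # presynaptic spike: LTD + transmitter
        B <- if (params$homeostasis) update_homeostatic_ltd(zht, params)
             else params$B
        apply_dw(-B * zm + params$delta)
        n_pre_here <- n_pre_here + 1L
      } else {                        # postsynaptic spike: LTP + hetero
        d <- if (freeze_w) (w0 - wtilde0) else (w - wt)
        apply_dw(params$A * zp * zs - params$beta * d * zm^3)
        n_post_here <- n_post_here + 1L
      }
      k <- k + 1L
    }
    zp <- zp + n_pre_here
    zm <- zm + n_post_here
    zs <- zs + n_post_here
    zht <- zht + n_post_here
    if (record) {
      traj_t <- c(traj_t, t); traj_w <- c(traj_w, w)
      traj_wt <- c(traj_wt, wt)
    }
  }
  advance_cons(t_end)

  out <- list(w = w, wtilde = wt, dw = dw, n_clamp = n_clamp)
  if (record)
    out$trajectory <- data.frame(t = traj_t, w = traj_w, wtilde = traj_wt)
  out
}

#' Poisson spike train with optional absolute refractory period
#'
#' @param rate rate in Hz.
#' @param t_end duration in seconds.
#' @param refractory absolute refractory period in seconds (0 = pure
#'   Poisson; with refractoriness the *output* rate matches `rate` by
#'   thinning-free hazard correction: inter-spike intervals are
#'   `refractory + Exp(1/rate_eff)` with `rate_eff = rate/(1 - rate*refractory)`).
#' @param n_spikes if non-`NULL`, generate exactly this many spikes instead
#'   of filling `t_end`.
#' @return sorted numeric vector of spike times.
#' @export
poisson_train <- function(rate, t_end = NULL, refractory = 0,
                          n_spikes = NULL) {
  if (rate <= 0) return(numeric(0))
  if (refractory > 0 && rate * refractory >= 1)
    stop("rate not attainable with this refractory period")
  rate_eff <- if (refractory > 0) rate / (1 - rate * refractory) else rate
  if (!is.null(n_spikes)) {
    isi <- refractory + stats::rexp(n_spikes, rate_eff)
    return(cumsum(isi))
  }
  n_guess <- max(10, ceiling(rate * t_end + 5 * sqrt(rate * t_end + 1)))
  times <- numeric(0)
  t_cur <- 0
  repeat {
    isi <- refractory + stats::rexp(n_guess, rate_eff)
    tt <- t_cur + cumsum(isi)
    times <- c(times, tt[tt <= t_end])
    t_cur <- tt[length(tt)]
    if (t_cur > t_end) break
  }
  times
}

#' Monte-Carlo estimate of the mean weight drift
#'
#' Simulates the event rule on independent Poisson pre/post trains at fixed
#' rates and a fixed operating point `d = w0 - wtilde0` (weight frozen), and
#' returns the mean drift `dw/dt` with its standard error over trials.
#' This is the simulation side of the drift-curve oracle.
#'
#' @param params an [exc_plasticity_params()] object.
#' @param nu_pre,nu_post rates in Hz.
#' @param d operating value of `w - wtilde`.
#' @param T_trial duration of one trial (s).
#' @param n_trials number of independent trials.
#' @return list with `drift` (mean dw/dt), `se`, and `trials`.
#' @export
mc_drift_estimate <- function(params, nu_pre, nu_post, d = 0.2,
                              T_trial = 100, n_trials = 8) {
  per_trial <- vapply(seq_len(n_trials), function(i) {
    pre <- poisson_train(nu_pre, T_trial)
    post <- poisson_train(nu_post, T_trial)
    res <- run_synapse_protocol(pre, post, params,
                                w0 = d, wtilde0 = 0,
                                t_end = T_trial, freeze_w = TRUE)
    res$dw / T_trial
  }, numeric(1))
  list(drift = mean(per_trial),
       se = stats::sd(per_trial) / sqrt(n_trials),
       trials = per_trial)
}
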