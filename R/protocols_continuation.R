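## rebuild the engine connection list of a trained network state, with the
## trained weights and reference weights as initial conditions
.continued_connections <- function(state, pp = state$pp, ppi = state$ppi,
                                   cons = state$cons,
                                   record_w_every = 10) {
  net <- state$net
  e <- net$edges
  list(
    input_e = connection(1, 2, e$input_e$pre, e$input_e$post,
                         state$w$input_e, "plastic_exc", params = pp,
                         consolidation = cons,
                         wtilde = state$wtilde$input_e,
                         record_w_every = record_w_every),
    e_e = connection(2, 2, e$e_e$pre, e$e_e$post, state$w$e_e,
                     "plastic_exc", params = pp, consolidation = cons,
                     wtilde = state$wtilde$e_e,
                     record_w_every = record_w_every),
    e_i = connection(2, 3, e$e_i$pre, e$e_i$post, state$w$e_i,
                     "static_exc"),
    i_e = connection(3, 2, e$i_e$pre, e$i_e$post, state$w$i_e,
                     "plastic_inh", params = ppi,
                     record_w_every = record_w_every),
    i_i = connection(3, 3, e$i_i$pre, e$i_i$post, state$w$i_i,
                     "static_inh"))
}

#' Storage of novel memories through directed stimulation
#'
#' Continues a trained network (see [run_assembly_formation()]): input from
#' the original modality is switched off and two pools R1/R2 -- drawn from
#' the reserve pool plus some neurons coding for old patterns -- are driven
#' through static synapses (`w = 0.2`, no short-term plasticity, 5\%
#' connectivity) from two new external Poisson populations.  Under the
#' usual stochastic stimulation paradigm the pools form new assemblies with
#' selective delay activity; restoring the original input afterwards leaves
#' the recall of the original assemblies intact.
#'
#' @param state `state` element of a [run_assembly_formation()] result.
#' @param t_stim duration (s) of R1/R2 stimulation (on 1 s / off 5 s, then
#'   brief-cue phase).
#' @param t_restore duration (s) after restoring the original input.
#' @param n_extra neurons coding for old patterns added to the reserve pool
#'   before the R1/R2 split.
#' @param seed RNG seed.
#' @return `protocol_result`; `summary` holds R1/R2 delay-activity scores
#'   during their recall phase and the original-assembly evoked
#'   selectivity after input restoration.
#' @export
run_novel_pattern_storage <- function(state, t_stim = 240, t_restore = 120,
                                      n_extra = 50, seed = 1) {
  net <- state$net
  n_exc <- net$n_exc
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  coding <- unlist(state$readouts$members)
  pool <- c(state$readouts$reserve,
            sample(coding, min(n_extra, length(coding))))
  pool <- unique(pool)
  half <- sample(pool, floor(length(pool) / 2))
  R1 <- sort(half); R2 <- sort(setdiff(pool, half))
  total_T <- t_stim + t_restore

  ## new-modality external pools (one per subset), 5% connectivity
  mk_ext <- function(R, pat_id, sch) {
    n <- length(R)
    e <- .sample_edges(n, n, 0.05)
    keep <- sch[sch$pattern == pat_id, , drop = FALSE]
    keep$pattern <- 1
    list(pop = pop_poisson(n, rate = 10,
                           stimulus = list(zeta = matrix(1, n, 1),
                                           schedule = keep,
                                           increment = 35)),
         pre = e$pre, post = R[e$post + 1])
  }
  phases <- data.frame(t_start = c(0, 0.6 * t_stim), T_on = c(1, 0.2),
                       T_off = c(5, 20))
  sch_new <- schedule_stimuli(t_stim, 2, burn_in = 5, phases = phases)
  ext1 <- mk_ext(R1, 1, sch_new)
  ext2 <- mk_ext(R2, 2, sch_new)
  ## original modality: silent during the R1/R2 phase (base rate 0),
  ## restored afterwards.  Restoration is expressed through augmented
  ## patterns at increment 45 Hz: a background column (10/45, giving the
  ## 10-Hz background) filling the gaps, and stimulus columns
  ## (10 + 35 zeta)/45 during cue epochs.
  sch_orig <- schedule_stimuli(total_T, ncol(state$zeta), T_on = 0.2,
                               T_off = 20, burn_in = t_stim + 5)
  zeta_aug <- cbind((10 + 35 * state$zeta) / 45,
                    bg = rep(10 / 45, net$n_input))
  bg_id <- ncol(zeta_aug)
  gaps_start <- c(t_stim, sch_orig$t_end)
  gaps_end <- c(sch_orig$t_start, total_T)
  keep <- gaps_end > gaps_start
  sch_aug <- rbind(sch_orig,
                   data.frame(pattern = bg_id,
                              t_start = gaps_start[keep],
                              t_end = gaps_end[keep]))
  sch_aug <- sch_aug[order(sch_aug$t_start), ]
  inp <- pop_poisson(net$n_input, rate = 0,
                     stimulus = list(zeta = zeta_aug, schedule = sch_aug,
                                     increment = 45))
  pops <- list(inp,
               pop_lif(n_exc, state$np, record_spikes = TRUE),
               pop_lif(net$n_inh, state$np),
               ext1$pop, ext2$pop)
  cns <- .continued_connections(state)
  cns$r1 <- connection(4, 2, ext1$pre, ext1$post, 0.2, "static_exc",
                       stp = FALSE)
  cns$r2 <- connection(5, 2, ext2$pre, ext2$post, 0.2, "static_exc",
                       stp = FALSE)
  res <- simulate_network(pops, cns, duration = total_T, seed = seed,
                          rate_bin = 1)
  raster <- res$spikes[[2]]
  ## delay activity of R1/R2 in their brief-cue phase
  rec_sch <- sch_new[sch_new$t_start >= 0.6 * t_stim, , drop = FALSE]
  score <- function(R, pat) {
    rows <- rec_sch[rec_sch$pattern == pat, , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    mean(vapply(seq_len(nrow(rows)), function(r) {
      tw <- c(rows$t_end[r] + 1, rows$t_end[r] + 4)
      mean(population_activity(raster, R, bin = diff(tw),
                               t_range = tw)$rate) > 5
    }, logical(1)))
  }
  ## original assemblies after restoration
  nu_post <- tryCatch(
    evoked_rates(raster, sch_orig, c(t_stim, total_T), n_exc),
    warning = function(w) NULL)
  orig_sel <- if (!is.null(nu_post)) {
    mean(vapply(seq_along(state$readouts$members), function(mu) {
      m <- state$readouts$members[[mu]] + 1L
      if (!length(m) || mu > ncol(nu_post)) return(NA_real_)
      mean(nu_post[m, mu], na.rm = TRUE)
    }, numeric(1)), na.rm = TRUE)
  } else NA_real_
  summary <- list(R1_delay = score(R1, 1), R2_delay = score(R2, 2),
                  n_R1 = length(R1), n_R2 = length(R2),
                  orig_evoked_after_restore = orig_sel)
  .protocol_result("novel_pattern_storage", seed,
                   list(t_stim = t_stim, t_restore = t_restore),
                   summary, rasters = list(exc = raster),
                   series = list(schedule_new = sch_new,
                                 schedule_orig = sch_orig))
}

#' Weight stability during prolonged recall of a single assembly
#'
#' Continues a trained network with external cueing switched off and the
#' transmitter-induced amplitude reduced to `delta = 1e-5` (which lowers
#' the firing rate of inactive assemblies to ~0.5 Hz and suppresses
#' spontaneous state transitions).  One assembly is activated by a single
#' brief cue and then stays continuously active; the recurrent weights of
#' the active assembly and all input weights stay approximately constant
#' while the recurrent weights of the inactive assemblies decay slowly.
#'
#' @param state `state` element of a [run_assembly_formation()] result.
#' @param duration simulated recall time (s).
#' @param active_pattern index of the assembly to keep active.
#' @param seed RNG seed.
#' @return `protocol_result`; `summary` holds the mean relative weight
#'   drifts of active/inactive recurrent and input connections and the
#'   inactive-assembly firing rate.
#' @export
run_prolonged_recall <- function(state, duration = 300,
                                 active_pattern = 1, seed = 1) {
  net <- state$net
  n_exc <- net$n_exc
  pp_low <- state$pp
  pp_low$delta <- 1e-5
  cue_sched <- data.frame(pattern = active_pattern, t_start = 5,
                          t_end = 5.5)
  inp <- pop_poisson(net$n_input, rate = 10,
                     stimulus = list(zeta = state$zeta,
                                     schedule = cue_sched,
                                     increment = 35))
  pops <- list(inp, pop_lif(n_exc, state$np, record_spikes = TRUE),
               pop_lif(net$n_inh, state$np))
  cns <- .continued_connections(state, pp = pp_low)
  res <- simulate_network(pops, cns, duration = duration, seed = seed,
                          rate_bin = 1)
  raster <- res$spikes[[2]]
  act_m <- state$readouts$members[[active_pattern]]
  inact_m <- setdiff(unlist(state$readouts$members), act_m)
  ee <- net$edges$e_e
  in_act <- ee$pre %in% act_m & ee$post %in% act_m
  in_inact <- ee$pre %in% inact_m & ee$post %in% inact_m
  drift <- function(w0, w1, sel) {
    if (!any(sel)) return(NA_real_)
    (mean(w1[sel]) - mean(w0[sel])) / max(mean(w0[sel]), 1e-9)
  }
  w_ee0 <- state$w$e_e; w_ee1 <- res$connections[[2]]$w
  w_in0 <- state$w$input_e; w_in1 <- res$connections[[1]]$w
  act_rate <- mean(population_activity(raster, act_m, bin = 5,
                                       t_range = c(10, duration))$rate)
  inact_rate <- if (length(inact_m))
    mean(population_activity(raster, inact_m, bin = 5,
                             t_range = c(10, duration))$rate) else NA_real_
  summary <- list(
    drift_active_recurrent = drift(w_ee0, w_ee1, in_act),
    drift_inactive_recurrent = drift(w_ee0, w_ee1, in_inact),
    drift_input = drift(w_in0, w_in1, rep(TRUE, length(w_in0))),
    active_rate = act_rate, inactive_rate = inact_rate)
  .protocol_result("prolonged_recall", seed,
                   list(duration = duration,
                        active_pattern = active_pattern),
                   summary, rasters = list(exc = raster),
                   series = list(e_e = res$connections[[2]]$series,
                                 input_e = res$connections[[1]]$series))
}

#' Associative recall from partial (occluded) cues
#'
#' Continues a trained network and probes memory recall with cues in which
#' three quarters of the input field are occluded (activation set to zero
#' outside one visible quadrant).  A probe counts as correct if the readout
#' population of the cued pattern is the most active one, above an absolute
#' floor, in the seconds following the cue.
#'
#' @param state `state` element of a [run_assembly_formation()] result.
#' @param n_probes number of occluded cues.
#' @param occlusion fraction of the field occluded (0.75 = one visible
#'   quadrant).
#' @param seed RNG seed.
#' @param rate_floor minimum readout-population rate (Hz) for a probe to
#'   count as an activation.
#' @return `protocol_result`; `summary` holds `correct_fraction`,
#'   `active_fraction` (some assembly activated) and the per-probe table.
#' @export
run_cue_recall <- function(state, n_probes = 8, occlusion = 0.75,
                           seed = 1, rate_floor = 5) {
  net <- state$net
  grid <- net$spec$input$grid
  nx <- grid[1]; ny <- grid[2]
  xs <- rep(seq_len(nx), times = ny)
  ys <- rep(seq_len(ny), each = nx)
  quadrant <- function(q) {
    switch(q,
           xs <= nx / 2 & ys <= ny / 2, xs > nx / 2 & ys <= ny / 2,
           xs <= nx / 2 & ys > ny / 2, xs > nx / 2 & ys > ny / 2)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n_pat <- ncol(state$zeta)
  probes <- data.frame(pattern = sample.int(n_pat, n_probes, replace = TRUE),
                       quadrant = sample.int(4, n_probes, replace = TRUE))
  ## occluded variants as extra stimulus columns; pick for each probe the
  ## quadrant with the largest remaining activation
  zeta_all <- state$zeta
  pat_col <- integer(n_probes)
  for (k in seq_len(n_probes)) {
    best_q <- which.max(vapply(1:4, function(q)
      sum(state$zeta[quadrant(q), probes$pattern[k]]), numeric(1)))
    mask <- quadrant(best_q)
    if (occlusion <= 0) mask <- rep(TRUE, nx * ny)
    zv <- state$zeta[, probes$pattern[k]] * as.numeric(mask)
    zeta_all <- cbind(zeta_all, zv)
    pat_col[k] <- ncol(zeta_all)
    probes$quadrant[k] <- best_q
  }
  t_gap <- 20
  sch <- data.frame(pattern = pat_col,
                    t_start = 10 + (seq_len(n_probes) - 1) * t_gap,
                    t_end = 10 + (seq_len(n_probes) - 1) * t_gap + 0.2)
  duration <- max(sch$t_end) + 10
  inp <- pop_poisson(net$n_input, rate = 10,
                     stimulus = list(zeta = zeta_all, schedule = sch,
                                     increment = 35))
  pops <- list(inp, pop_lif(net$n_exc, state$np, record_spikes = TRUE),
               pop_lif(net$n_inh, state$np))
  cns <- .continued_connections(state, record_w_every = 0)
  res <- simulate_network(pops, cns, duration = duration, seed = seed)
  raster <- res$spikes[[2]]
  probes$correct <- NA
  probes$active <- NA
  for (k in seq_len(n_probes)) {
    tw <- c(sch$t_end[k] + 0.3, sch$t_end[k] + 3.3)
    acts <- vapply(seq_len(n_pat), function(mu) {
      m <- state$readouts$members[[mu]]
      if (!length(m)) return(0)
      mean(population_activity(raster, m, bin = diff(tw),
                               t_range = tw)$rate)
    }, numeric(1))
    probes$active[k] <- max(acts) > rate_floor
    probes$correct[k] <- probes$active[k] &&
      which.max(acts) == probes$pattern[k]
  }
  summary <- list(correct_fraction = mean(probes$correct),
                  active_fraction = mean(probes$active),
                  probes = probes)
  .protocol_result("cue_recall", seed,
                   list(n_probes = n_probes, occlusion = occlusion),
                   summary, rasters = list(exc = raster))
}
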