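## Assemble engine population/connection lists for a balanced network.
## Population order: 1 = input (Poisson), 2 = excitatory, 3 = inhibitory,
## followed by any extra populations appended by the caller.
.network_populations <- function(net, np, input_rate = 10, stimulus = NULL,
                                 record_input = FALSE) {
  list(pop_poisson(net$n_input, rate = input_rate, stimulus = stimulus,
                   record_spikes = record_input),
       pop_lif(net$n_exc, np, record_spikes = TRUE),
       pop_lif(net$n_inh, np, record_spikes = TRUE))
}

.network_connections <- function(net, plastic = list(),
                                 pp = exc_plasticity_params(),
                                 ppi = inh_plasticity_params(),
                                 cons = consolidation_params(),
                                 wtilde0 = NULL,
                                 plasticity_start = 0,
                                 record_w_every = 10) {
  e <- net$edges
  mk_exc <- function(edge, src, dst, class) {
    if (isTRUE(plastic[[class]])) {
      connection(src, dst, edge$pre, edge$post, edge$w, "plastic_exc",
                 params = pp, consolidation = cons,
                 wtilde = if (is.null(wtilde0)) NULL
                          else rep(wtilde0, length(edge$pre)),
                 plasticity_start = plasticity_start,
                 record_w_every = record_w_every)
    } else {
      connection(src, dst, edge$pre, edge$post, edge$w, "static_exc")
    }
  }
  cns <- list(
    input_e = mk_exc(e$input_e, 1, 2, "input_e"),
    e_e = mk_exc(e$e_e, 2, 2, "e_e"),
    e_i = connection(2, 3, e$e_i$pre, e$e_i$post, e$e_i$w, "static_exc"))
  if (isTRUE(plastic$i_e)) {
    cns$i_e <- connection(3, 2, e$i_e$pre, e$i_e$post, e$i_e$w,
                          "plastic_inh", params = ppi,
                          plasticity_start = plasticity_start,
                          record_w_every = record_w_every)
  } else {
    cns$i_e <- connection(3, 2, e$i_e$pre, e$i_e$post, e$i_e$w,
                          "static_inh")
  }
  cns$i_i <- connection(3, 3, e$i_i$pre, e$i_i$post, e$i_i$w, "static_inh")
  cns
}

#' Embedded-assembly demonstration: working memory and runaway plasticity
#'
#' A balanced network with one embedded cell assembly (intra-assembly
#' recurrent weights preset stronger).  A brief (300 ms) external cue to
#' the assembly triggers persistent selective delay activity.  Without
#' plasticity the network functions as a working memory; with plain triplet
#' STDP on the recurrent excitatory synapses (`plastic = TRUE`, no
#' heterosynaptic or transmitter-induced terms, no inhibitory plasticity)
#' the assembly rate explodes within ~100 s and the background follows.
#'
#' @param plastic enable triplet STDP on the recurrent E-E synapses.
#' @param cue apply the 300-ms cue (no cue: no delay-activity onset).
#' @param n_exc,n_inh,assembly_size network scale.
#' @param duration simulated time after the cue (s).
#' @param cue_time cue onset (s).
#' @param seed RNG seed.
#' @param np neuron parameters.
#' @param A triplet amplitude on the plastic variant.
#' @param weights initial weights per class (see [network_spec()]); the
#'   defaults are tuned for bistable delay activity at this scale.
#' @param w_assembly preset intra-assembly weight.
#' @return `protocol_result`; `summary` holds the assembly and background
#'   rates early/late and their ratio; `series` the population activities.
#' @export
run_fig1_failure_demo <- function(plastic = FALSE, cue = TRUE,
                                  n_exc = 512, n_inh = 128,
                                  assembly_size = 128,
                                  duration = 100, cue_time = 10, seed = 1,
                                  np = neuron_params(), A = 1e-3,
                                  weights = list(input_e = 0.34, e_e = 0.15,
                                                 e_i = 0.5, i_e = 0.8,
                                                 i_i = 1.5),
                                  w_assembly = 3.5, cue_rate = 500,
                                  w_cue = 2) {
  spec <- network_spec(n_exc, n_inh, p_rec = 0.2,
                       input = list(mode = "sparse", n_input = n_exc,
                                    p = 0.1),
                       weights = weights)
  net <- build_network(spec, seed)
  members <- 0:(assembly_size - 1)
  net <- embed_assembly(net, members, w_assembly)
  pops <- .network_populations(net, np)
  cns <- .network_connections(net, plastic = list())
  if (plastic) {
    pp_trip <- exc_plasticity_params(A = A, beta = 0, delta = 0)
    ee <- net$edges$e_e
    cns$e_e <- connection(2, 2, ee$pre, ee$post, ee$w, "plastic_exc",
                          params = pp_trip, record_w_every = 5)
  }
  ## cue population: one Poisson unit per assembly member, silent except
  ## during the 300-ms cue window
  total_T <- cue_time + duration
  if (cue) {
    cue_sched <- data.frame(pattern = 1, t_start = cue_time,
                            t_end = cue_time + 0.3)
    cue_pop <- pop_poisson(assembly_size, rate = 0,
                           stimulus = list(zeta = matrix(1, assembly_size, 1),
                                           schedule = cue_sched,
                                           increment = cue_rate))
    pops <- c(pops, list(cue_pop))
    cns$cue <- connection(4, 2, members, members, w_cue, "static_exc",
                          stp = FALSE)
  }
  res <- simulate_network(pops, cns, duration = total_T, seed = seed,
                          rate_bin = 1)
  raster <- res$spikes[[2]]
  act_asm <- population_activity(raster, members, bin = 1,
                                 t_range = c(0, total_T))
  act_bg <- population_activity(raster, setdiff(0:(n_exc - 1), members),
                                bin = 1, t_range = c(0, total_T))
  early <- act_asm$t > cue_time + 1 & act_asm$t < cue_time + 11
  late <- act_asm$t > total_T - 10
  summary <- list(
    assembly_rate_early = mean(act_asm$rate[early]),
    assembly_rate_late = mean(act_asm$rate[late]),
    background_rate_early = mean(act_bg$rate[early]),
    background_rate_late = mean(act_bg$rate[late]),
    assembly_rate_max = max(act_asm$rate[act_asm$t > cue_time]),
    growth_ratio = mean(act_asm$rate[late]) /
      max(mean(act_asm$rate[early]), 1e-9),
    pre_cue_assembly_rate = mean(act_asm$rate[act_asm$t < cue_time]))
  .protocol_result("fig1_failure_demo", seed,
                   list(plastic = plastic, cue = cue, n_exc = n_exc,
                        n_inh = n_inh, assembly_size = assembly_size,
                        duration = duration, weights = weights,
                        w_assembly = w_assembly),
                   summary,
                   rasters = list(exc = raster),
                   series = list(assembly = act_asm, background = act_bg))
}

#' Assembly formation and recall in the full plastic network
#'
#' The complete model: receptive-field structured input from a Poisson
#' grid, orchestrated plasticity on afferent and recurrent excitatory
#' synapses, globally modulated inhibitory plasticity, consolidation --
#' all permanently active.  The network is stimulated with overlapping
#' binary shape patterns (learning phase, mean on 1 s / off 2 s), then the
#' paradigm switches to brief cues with long intervals (recall phase, on
#' 0.2 s / off 20 s) to test selective delay activity.
#'
#' @param n_exc,n_inh network scale.
#' @param grid,radius input grid and receptive-field radius.
#' @param n_patterns number of shape patterns.
#' @param t_learn,t_recall durations (s) of the learning and recall phases.
#' @param burn_in unstimulated burn-in (s).
#' @param seed RNG seed.
#' @param np,pp,ppi,cons model parameters.
#' @param weights initial weights per class.
#' @param readout_window window (s, relative to run start) for computing
#'   evoked rates; defaults to the last 40\% of the learning phase.
#' @return `protocol_result`; `summary` holds readout sizes, delay-activity
#'   statistics of the recall phase and background rates; `series` the
#'   weight trajectories.
#' @export
run_assembly_formation <- function(n_exc = 512, n_inh = 128, p_rec = 0.4,
                                   grid = c(64, 64), radius = 8,
                                   n_patterns = 4,
                                   t_learn = 600, t_recall = 200,
                                   burn_in = 50, seed = 1,
                                   np = neuron_params(),
                                   pp = exc_plasticity_params(),
                                   ppi = inh_plasticity_params(eta = 5e-3),
                                   cons = NULL,
                                   weights = list(input_e = 0.2, e_e = 0.05,
                                                  e_i = 2, i_e = 2,
                                                  i_i = 0.5),
                                   readout_window = NULL) {
  if (is.null(cons))
    cons <- suppressWarnings(consolidation_params(tau_cons = 240))
  spec <- network_spec(n_exc, n_inh, p_rec = p_rec,
                       input = list(mode = "rf", grid = grid,
                                    radius = radius),
                       weights = weights)
  net <- build_network(spec, seed)
  zeta <- make_shape_patterns(grid, n_patterns, seed = seed)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed + 1)
  total_T <- t_learn + t_recall
  phases <- data.frame(t_start = c(0, t_learn), T_on = c(1, 0.2),
                       T_off = c(2, 20))
  sch <- schedule_stimuli(total_T, n_patterns, burn_in = burn_in,
                          phases = phases)
  pops <- .network_populations(net, np,
                               stimulus = list(zeta = zeta, schedule = sch,
                                               increment = 35))
  cns <- .network_connections(net,
                              plastic = list(input_e = TRUE, e_e = TRUE,
                                             i_e = TRUE),
                              pp = pp, ppi = ppi, cons = cons)
  res <- simulate_network(pops, cns, duration = total_T, seed = seed,
                          rate_bin = 1)
  raster <- res$spikes[[2]]
  if (is.null(readout_window))
    readout_window <- c(t_learn - 0.4 * t_learn, t_learn)
  nu <- evoked_rates(raster, sch, readout_window, n_exc)
  ro <- assign_readouts(nu)
  ## delay activity: fraction of recall-phase off intervals (>= 5 s) in
  ## which some readout population stays above threshold
  rec_sch <- sch[sch$t_start >= t_learn, , drop = FALSE]
  delay_scores <- c(); correct <- c(); bg_rates <- c()
  if (nrow(rec_sch) >= 2) {
    for (r in seq_len(nrow(rec_sch) - 1)) {
      gap <- c(rec_sch$t_end[r], rec_sch$t_start[r + 1])
      if (diff(gap) < 5) next
      probe <- gap[1] + c(0.25 * diff(gap), 0.75 * diff(gap))
      mu <- rec_sch$pattern[r]
      acts <- vapply(seq_along(ro$members), function(m) {
        if (length(ro$members[[m]]) == 0) return(0)
        mean(population_activity(raster, ro$members[[m]], bin = diff(probe),
                                 t_range = probe)$rate)
      }, numeric(1))
      delay_scores <- c(delay_scores, max(acts) > 5)
      correct <- c(correct, which.max(acts) == mu && max(acts) > 5)
      others <- setdiff(0:(n_exc - 1), unlist(ro$members))
      if (length(others)) {
        bg_rates <- c(bg_rates,
                      mean(population_activity(raster, others,
                                               bin = diff(probe),
                                               t_range = probe)$rate))
      }
    }
  }
  summary <- list(
    n_readout = lengths(ro$members),
    n_reserve = length(ro$reserve),
    delay_activity_fraction = if (length(delay_scores))
      mean(delay_scores) else NA_real_,
    correct_delay_fraction = if (length(correct)) mean(correct) else
      NA_real_,
    background_rate_delay = if (length(bg_rates)) mean(bg_rates) else
      NA_real_,
    n_delay_probes = length(delay_scores))
  .protocol_result("assembly_formation", seed,
                   list(n_exc = n_exc, n_inh = n_inh, grid = grid,
                        radius = radius, n_patterns = n_patterns,
                        t_learn = t_learn, t_recall = t_recall,
                        weights = weights),
                   summary,
                   rasters = list(exc = raster),
                   weights = list(
                     e_e = list(pre = res$connections[[2]]$pre,
                                post = res$connections[[2]]$post,
                                w = res$connections[[2]]$w,
                                wtilde = res$connections[[2]]$wtilde,
                                n_pre = n_exc, n_post = n_exc,
                                class = "e_e"),
                     input_e = list(pre = res$connections[[1]]$pre,
                                    post = res$connections[[1]]$post,
                                    w = res$connections[[1]]$w,
                                    wtilde = res$connections[[1]]$wtilde,
                                    n_pre = net$n_input, n_post = n_exc,
                                    class = "input_e")),
                   series = list(input_e = res$connections[[1]]$series,
                                 e_e = res$connections[[2]]$series,
                                 i_e = res$connections[[4]]$series,
                                 schedule = sch, readouts = ro,
                                 evoked_rates = nu)) -> out
  ## trained state for continuation protocols
  w_final <- lapply(res$connections, `[[`, "w")
  wt_final <- lapply(res$connections, `[[`, "wtilde")
  names(w_final) <- names(wt_final) <- c("input_e", "e_e", "e_i", "i_e",
                                         "i_i")
  out$state <- list(net = net, zeta = zeta, w = w_final, wtilde = wt_final,
                    readouts = ro, np = np, pp = pp, ppi = ppi,
                    cons = cons)
  out
}

#' Consolidation blockade experiment
#'
#' Two identical networks are prepared with three blocks of input neurons
#' strongly connected to equally sized blocks of network neurons (all
#' reference weights start at zero, recurrent connectivity unstructured).
#' After a learning period the mean interstimulus interval is increased
#' (off 2 s to 20 s).  In the control network the external cues keep
#' reliably switching the active assembly; with the consolidation dynamics
#' blocked (reference weights frozen), input and recurrent assembly
#' weights decay and the network decouples from the input.
#'
#' @param blocked freeze the reference weights (`TRUE`) or run the control.
#' @param n_exc,n_inh network scale; `block_size` neurons per assembly
#'   block (3 blocks).
#' @param t_learn learning time before the interval switch (s).
#' @param t_probe probe time after the switch (s).
#' @param seed RNG seed (use the same seed for the pair).
#' @param np,pp,ppi,cons model parameters.
#' @param w_block initial strong input weight inside the blocks.
#' @return `protocol_result`; `summary` holds the cue-response reliability
#'   in the probe phase and the mean input/recurrent assembly weights at
#'   the switch and at the end.
#' @export
run_consolidation_blockade <- function(blocked = FALSE,
                                       n_exc = 240, n_inh = 60,
                                       block_size = 40,
                                       t_learn = 300, t_probe = 200,
                                       seed = 1,
                                       np = neuron_params(),
                                       pp = exc_plasticity_params(),
                                       ppi = inh_plasticity_params(eta = 5e-3),
                                       cons = NULL,
                                       w_block = 1.2, p_block = 0.5) {
  n_blocks <- 3
  if (is.null(cons))
    cons <- suppressWarnings(consolidation_params(tau_cons = 240))
  spec <- network_spec(n_exc, n_inh, p_rec = 0.2,
                       input = list(mode = "sparse", n_input = n_exc,
                                    p = 0.3),
                       weights = list(input_e = 0.4, e_e = 0.1,
                                      e_i = 2, i_e = 2, i_i = 0.5))
  net <- build_network(spec, seed)
  ## strong, dense block-diagonal input structure on top of the sparse
  ## background wiring: input block k -> network block k at p_block
  ie <- net$edges$input_e
  blk_in <- ie$pre %/% block_size
  blk_out <- ie$post %/% block_size
  keep <- !(blk_in == blk_out & blk_in < n_blocks)  # drop in-block sparse
  ie <- lapply(ie, `[`, keep)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv),
          add = TRUE)
  set.seed(seed + 7)
  blk_pre <- blk_post <- integer(0)
  for (k in seq_len(n_blocks)) {
    e <- .sample_edges(block_size, block_size, p_block)
    blk_pre <- c(blk_pre, e$pre + (k - 1L) * block_size)
    blk_post <- c(blk_post, e$post + (k - 1L) * block_size)
  }
  net$edges$input_e <- list(pre = c(ie$pre, blk_pre),
                            post = c(ie$post, blk_post),
                            w = c(ie$w, rep(w_block, length(blk_pre))))
  sel <- c(rep(FALSE, length(ie$pre)), rep(TRUE, length(blk_pre)))
  zeta <- matrix(0, net$n_input, n_blocks)
  for (k in seq_len(n_blocks))
    zeta[(k - 1) * block_size + seq_len(block_size), k] <- 1
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed + 1)
  total_T <- t_learn + t_probe
  phases <- data.frame(t_start = c(0, t_learn), T_on = c(1, 1),
                       T_off = c(2, 20))
  sch <- schedule_stimuli(total_T, n_blocks, burn_in = 50, phases = phases)
  pops <- .network_populations(net, np,
                               stimulus = list(zeta = zeta, schedule = sch,
                                               increment = 35))
  cons_used <- cons
  if (blocked) cons_used$freeze_t <- 0
  cns <- .network_connections(net,
                              plastic = list(input_e = TRUE, e_e = TRUE,
                                             i_e = TRUE),
                              pp = pp, ppi = ppi, cons = cons_used,
                              wtilde0 = 0)
  res <- simulate_network(pops, cns, duration = total_T, seed = seed,
                          rate_bin = 1)
  raster <- res$spikes[[2]]
  members <- lapply(seq_len(n_blocks), function(k)
    (k - 1) * block_size + seq_len(block_size) - 1L)
  ## cue-response reliability in the probe phase: a cue counts as a switch
  ## if the cued block's activity in the second after the cue exceeds both
  ## 5 Hz and all other blocks' activity
  probe_sch <- sch[sch$t_start >= t_learn + 5, , drop = FALSE]
  hits <- logical(0)
  for (r in seq_len(nrow(probe_sch))) {
    tw <- c(probe_sch$t_start[r], probe_sch$t_end[r] + 1)
    acts <- vapply(members, function(m)
      mean(population_activity(raster, m, bin = diff(tw),
                               t_range = tw)$rate), numeric(1))
    hits <- c(hits, which.max(acts) == probe_sch$pattern[r] &&
                max(acts) > 5)
  }
  in_blk <- sel
  ee <- net$edges$e_e
  rec_blk <- ee$pre %/% block_size == ee$post %/% block_size &
    ee$pre %/% block_size < n_blocks
  w_in_final <- mean(res$connections[[1]]$w[in_blk])
  w_rec_final <- mean(res$connections[[2]]$w[rec_blk])
  summary <- list(
    blocked = blocked,
    switch_reliability = if (length(hits)) mean(hits) else NA_real_,
    n_probes = length(hits),
    mean_input_block_w_final = w_in_final,
    mean_recurrent_block_w_final = w_rec_final,
    input_series = res$connections[[1]]$series$mean_w,
    series_t = res$connections[[1]]$series$t)
  .protocol_result("consolidation_blockade", seed,
                   list(blocked = blocked, n_exc = n_exc,
                        block_size = block_size, t_learn = t_learn,
                        t_probe = t_probe, w_block = w_block),
                   summary,
                   rasters = list(exc = raster),
                   series = list(input_e = res$connections[[1]]$series,
                                 e_e = res$connections[[2]]$series,
                                 schedule = sch))
}
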