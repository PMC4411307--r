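test_that("pairing curves: classic STDP signs and triplet equivalence", {
  pc <- run_pairing_curves(frequencies = c(1, 5, 10, 20, 40, 50))
  ## no pairings: no change
  pc0 <- run_pairing_curves(frequencies = 10, n_pairs = 0)
  expect_true(all(pc0$dw_orchestrated == 0))
  expect_true(all(pc0$dw_triplet == 0))
  ## pure triplet, low frequency, post-before-pre: net depression
  low_neg <- pc$freq <= 5 & pc$dt < 0
  expect_true(all(pc$dw_triplet[low_neg] < 0))
  ## high pairing frequency: potentiation for both timings (triplet LTP)
  expect_true(all(pc$dw_triplet[pc$freq == 50] > 0))
  ## below 40 Hz the orchestrated rule tracks the triplet rule to within
  ## 10% of the curve's scale
  sel <- pc$freq < 40
  scale <- max(abs(pc$dw_triplet[sel]))
  expect_lt(max(abs(pc$dw_orchestrated[sel] - pc$dw_triplet[sel])),
            0.1 * scale)
  ## at high frequency heterosynaptic braking keeps the orchestrated
  ## change below the triplet one
  hi <- pc$freq == 50 & pc$dt > 0
  expect_lt(pc$dw_orchestrated[hi], pc$dw_triplet[hi])
})

test_that("stochastic high-rate trains: orchestrated change smaller than
           pure triplet", {
  ## Poisson pre/post at matched rates with 5-ms refractoriness, duration
  ## scaled to 100 expected spikes per train
  set.seed(21)
  pp <- exc_plasticity_params()
  pp_trip <- exc_plasticity_params(beta = 0, delta = 0)
  rate <- 40
  dw_o <- dw_t <- numeric(20)
  for (k in 1:20) {
    T_end <- 100 / rate
    pre <- poisson_train(rate, T_end, refractory = 5e-3)
    post <- poisson_train(rate, T_end, refractory = 5e-3)
    dw_o[k] <- run_synapse_protocol(pre, post, pp, w0 = 0.5,
                                    wtilde0 = 0.3, t_end = T_end)$w - 0.5
    dw_t[k] <- run_synapse_protocol(pre, post, pp_trip, w0 = 0.5,
                                    wtilde0 = 0.3, t_end = T_end)$w - 0.5
  }
  expect_lt(mean(dw_o), mean(dw_t))
  expect_gt(mean(dw_t), 0)
})

test_that("postsynaptic tetanization is bidirectional around the reference
           weight", {
  res <- run_tetanization(seed = 1)
  s <- res$summary
  expect_lt(s$correlation, -0.5)
  expect_lt(s$mean_dw_w_gt_wt, 0)   # strong synapses depress
  expect_gt(s$mean_dw_w_lt_wt, 0)   # weak synapses potentiate
  expect_lt(s$mean_abs_rel_change_w_eq_wt, 0.05)
})

test_that("single-neuron bistability converges to the branch chosen by the
           initial weight", {
  ## short diagnostic runs; the full-length experiment is exercised by the
  ## acceptance suite
  hi <- run_single_neuron_bistability(0.35, duration = 240, seed = 2)
  lo <- run_single_neuron_bistability(0.20, duration = 240, seed = 2)
  expect_gt(hi$summary$rate, 10)
  expect_lt(lo$summary$rate, 5)
  expect_gt(hi$summary$rate, 4 * max(lo$summary$rate, 0.5))
  ## beta sweep: the upper fixed-point rate decreases with beta
  hi_strong <- run_single_neuron_bistability(
    0.35, duration = 240, seed = 2,
    pp = exc_plasticity_params(beta = 3 * exc_plasticity_params()$beta))
  expect_lt(hi_strong$summary$rate, hi$summary$rate)
})

test_that("localized stimulation imprints stimulus-locked weight structure", {
  ## weights of inputs with high cumulative bump exposure grow relative to
  ## rarely stimulated inputs (full single-bump localization needs hours
  ## of simulated time; see the methods vignette)
  rf <- run_receptive_field_formation(n_inputs = 1000, duration = 600,
                                      sigma = 50, seed = 2,
                                      cons = suppressWarnings(
                                        consolidation_params(tau_cons = 240)))
  zeta <- make_gaussian_profile_stimuli(1000, 50, 10, seed = 2)
  expo <- rowMeans(zeta)
  w <- rf$weights$input$w
  o <- order(-expo)
  expect_gt(mean(w[o[1:100]]), 1.3 * mean(w[o[901:1000]]))
  expect_true(all(w >= 0 & w <= 5))
  expect_true(rf$summary$localization >= 0 && rf$summary$localization <= 1)
})

test_that("novel subsets can be driven through a second input modality", {
  ## smoke-scale continuation: structure and score ranges only
  r <- run_assembly_formation(n_exc = 128, n_inh = 32, t_learn = 80,
                              t_recall = 20, burn_in = 20, seed = 2)
  nv <- run_novel_pattern_storage(r$state, t_stim = 60, t_restore = 30,
                                  seed = 3)
  s <- nv$summary
  expect_gt(s$n_R1 + s$n_R2, 10)
  for (v in c(s$R1_delay, s$R2_delay))
    expect_true(is.na(v) || (v >= 0 && v <= 1))
})

test_that("protocol results are reproducible and serializable", {
  r1 <- run_single_neuron_bistability(0.3, duration = 30, seed = 9)
  r2 <- run_single_neuron_bistability(0.3, duration = 30, seed = 9)
  expect_identical(r1$rasters, r2$rasters)
  expect_identical(r1$summary, r2$summary)
  dir <- tempfile()
  write_protocol_result(r1, dir)
  back <- read_protocol_result(dir)
  expect_equal(nrow(back$rasters$post), nrow(r1$rasters$post))
  expect_equal(back$summary$rate, r1$summary$rate)
})
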