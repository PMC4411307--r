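test_that("a spike is first visible postsynaptically one delay later", {
  ## huge synapse: the target fires on the step the spike is delivered
  src <- pop_spike_source(1, times = 0.1, ids = 0, record_spikes = TRUE)
  post <- pop_lif(1, neuron_params())
  cn <- connection(1, 2, 0, 0, w = 50, type = "static_exc", stp = FALSE)
  for (delay in c(8e-4, 3e-3)) {
    r <- simulate_network(list(src, post), list(cn), duration = 0.2,
                          seed = 1, delay = delay)
    t_post <- r$spikes[[2]]$time[1]
    expect_gte(t_post, 0.1 + delay)
    expect_lt(t_post, 0.1 + delay + 1e-3)
  }
})

test_that("empty network advances with no spikes", {
  r <- simulate_network(list(pop_lif(3, neuron_params())), list(),
                        duration = 0.01, seed = 1)
  expect_equal(r$n_steps, 100)
  expect_equal(nrow(r$spikes[[1]]), 0L)
})

test_that("unregistered connection endpoints fail at build time", {
  cn <- connection(1, 3, 0, 0, 0.1, "static_exc")
  expect_error(simulate_network(list(pop_lif(1, neuron_params())),
                                list(cn), 0.1), "not registered")
})

test_that("engine plasticity matches the event-driven reference exactly", {
  ## prescribed presynaptic spikes onto a regularly firing neuron; the
  ## engine's event updates must agree with the exact event-driven
  ## integration once pre spikes are shifted by the conduction delay
  delay <- 8e-4
  set.seed(31)
  pre_times <- sort(round(runif(80, 0.05, 4.95), 3))
  pp <- exc_plasticity_params(beta = 0.02, delta = 1e-4)
  src <- pop_spike_source(1, times = pre_times, ids = rep(0, 80))
  post <- pop_lif(1, neuron_params(delta_a = 0, theta_jump = 0,
                                   I_ext = 25e-3))
  cn <- connection(1, 2, 0, 0, w = 0.4, type = "plastic_exc", stp = FALSE,
                   params = pp, wtilde = 0.3)
  r <- simulate_network(list(src, post), list(cn), duration = 5, seed = 1,
                        delay = delay)
  post_times <- r$spikes[[2]]$time
  expect_gt(length(post_times), 100)
  ## delivery times quantized to the dt grid exactly as the engine does,
  ## so simultaneous pre/post events share one timestamp
  pre_delivered <- round((pre_times + delay) / 1e-4) * 1e-4
  ref <- run_synapse_protocol(pre_delivered, post_times, pp,
                              w0 = 0.4, wtilde0 = 0.3, t_end = 5)
  expect_equal(r$connections[[1]]$w, ref$w, tolerance = 1e-10)
})

test_that("recorded weight series and clamp counters are returned", {
  src <- pop_poisson(10, rate = 20)
  post <- pop_lif(1, neuron_params(I_ext = 25e-3))
  cn <- connection(1, 2, 0:9, rep(0, 10), 0.2, "plastic_exc",
                   record_w_every = 0.5, record_syn = c(1, 5))
  r <- simulate_network(list(src, post), list(cn), duration = 4, seed = 2)
  ser <- r$connections[[1]]$series
  expect_equal(length(ser$t), 8)
  expect_true(all(is.finite(ser$mean_w)))
  expect_equal(dim(ser$syn_w), c(8L, 2L))
  expect_gte(r$connections[[1]]$clamp_count, 0)
})
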