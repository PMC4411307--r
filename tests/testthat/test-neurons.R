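test_that("constant suprathreshold drive reproduces the closed-form LIF rate", {
  for (I in c(25e-3, 40e-3)) {
    np <- neuron_params(delta_a = 0, theta_jump = 0, I_ext = I)
    r <- simulate_network(list(pop_lif(1, np)), list(), duration = 3,
                          seed = 1)
    isi <- diff(r$spikes[[1]]$time)
    expect_equal(mean(isi), lif_isi_analytic(I), tolerance = 0.02)
  }
})

test_that("resting neuron stays silent and spiking is deterministic", {
  np <- neuron_params()
  r <- simulate_network(list(pop_lif(5, np)), list(), duration = 1, seed = 1)
  expect_equal(nrow(r$spikes[[1]]), 0L)
  ## determinism of Poisson-driven spiking
  p <- pop_poisson(50, rate = 10, record_spikes = TRUE)
  r1 <- simulate_network(list(p), list(), 20, seed = 3)
  r2 <- simulate_network(list(p), list(), 20, seed = 3)
  r3 <- simulate_network(list(p), list(), 20, seed = 4)
  expect_identical(r1$spikes, r2$spikes)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("spike-frequency adaptation slows firing over the first seconds", {
  np <- neuron_params(I_ext = 30e-3)  # adaptation on by default
  r <- simulate_network(list(pop_lif(1, np)), list(), duration = 6, seed = 1)
  st <- r$spikes[[1]]$time
  r_early <- sum(st < 0.5) / 0.5
  r_mid <- sum(st >= 1 & st < 3) / 2
  r_late <- sum(st >= 4) / 2
  expect_gt(r_early, r_mid)
  expect_gte(r_mid, r_late)
  expect_gt(r_late, 0)
})

test_that("slow second adaptation decays sustained firing over tens of seconds", {
  np <- neuron_params(I_ext = 25e-3, delta_a2 = 0.02, tau_adapt2 = 20)
  r <- simulate_network(list(pop_lif(1, np)), list(), duration = 60, seed = 1)
  st <- r$spikes[[1]]$time
  rate_bins <- vapply(seq(0, 50, by = 10), function(t0)
    sum(st >= t0 & st < t0 + 10) / 10, numeric(1))
  expect_true(all(diff(rate_bins) <= 0.5))  # monotone decline (with slack)
  expect_lt(rate_bins[6], rate_bins[1] / 2)
})

test_that("poisson_spikes has the right rate and rejects negative rates", {
  set.seed(1)
  hits <- sum(replicate(2000, sum(poisson_spikes(50, 10, 1e-3))))
  expect_equal(hits / (2000 * 50 * 1e-3), 10, tolerance = 0.1)
  expect_error(poisson_spikes(10, -1, 1e-3), "non-negative")
  expect_true(!any(poisson_spikes(100, 0, 1e-3)))
})

test_that("empirical Poisson population rate matches 10 Hz over 100 s", {
  p <- pop_poisson(50, rate = 10, record_spikes = TRUE)
  r <- simulate_network(list(p), list(), duration = 100, seed = 12)
  expect_equal(nrow(r$spikes[[1]]) / (50 * 100), 10, tolerance = 0.05)
})
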