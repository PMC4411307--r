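test_that("secreted factor decays analytically and tracks the population rate", {
  pp <- inh_plasticity_params(tau_H = 10)
  ## pure decay over one time constant, integrated in steps
  H <- 1
  for (k in 1:10000) H <- step_global_factor(H, 0, 1e-3, pp, 100)$H
  expect_equal(H, exp(-1), tolerance = 1e-3)
  ## steady state at a constant population rate equals the per-neuron rate
  n_exc <- 200; rate <- 4; dt <- 1e-3
  H <- 0
  for (k in 1:120000) H <- step_global_factor(H, n_exc * rate * dt, dt, pp,
                                              n_exc)$H
  expect_equal(H, rate, tolerance = 0.01)
})

test_that("G gates the sign of every update", {
  pp <- inh_plasticity_params()
  expect_equal(step_global_factor(2, 0, 1e-4, pp, 10)$G < 0, TRUE)
  ## G = 0: no change at all
  expect_equal(inh_pair_update(c(0.2, 1), c(3, 5), G = 0, pp), c(0.2, 1))
  ## G < 0: sign audit over simulated Poisson pair events
  set.seed(5)
  w <- rep(0.5, 50)
  for (k in 1:200) {
    z <- rexp(50, 2)
    w_new <- inh_pair_update(w, z, G = -1.5, pp)
    expect_true(all(w_new <= w))
    expect_true(all(w_new >= 0))
    w <- w_new
  }
  ## G > 0 with active traces: net potentiation
  expect_gt(inh_pair_update(0.5, 0.4, G = 2, pp), 0.5)
})

test_that("closed-loop inhibitory plasticity relaxes activity towards gamma", {
  ## small E-I loop driven too hard: H starts above gamma, inhibitory
  ## weights grow, and the excitatory rate comes down towards the target
  np <- neuron_params()
  ppi <- inh_plasticity_params(eta = 5e-3, tau_H = 2, gamma = 3)
  ne <- 80; ni <- 20
  set.seed(9)
  e_in <- plastinet:::.sample_edges(ne, ne, 0.4)
  e_ei <- plastinet:::.sample_edges(ne, ni, 0.4)
  e_ie <- plastinet:::.sample_edges(ni, ne, 0.4)
  pops <- list(pop_poisson(ne, rate = 30),
               pop_lif(ne, np), pop_lif(ni, np))
  cns <- list(
    connection(1, 2, e_in$pre, e_in$post, 0.7, "static_exc"),
    connection(2, 3, e_ei$pre, e_ei$post, 1, "static_exc"),
    connection(3, 2, e_ie$pre, e_ie$post, 0.2, "plastic_inh", params = ppi,
               record_w_every = 5))
  res <- simulate_network(pops, cns, duration = 120, seed = 4, rate_bin = 10)
  e_rates <- res$rates[, 2]
  expect_gt(e_rates[1], ppi$gamma + 2)          # driven too hard initially
  expect_lt(tail(e_rates, 1), e_rates[1] * 0.7) # relaxes downwards
  expect_lt(abs(tail(res$connections[[3]]$series$H, 1) - ppi$gamma), 2)
  w_ser <- res$connections[[3]]$series$mean_w
  expect_gt(tail(w_ser, 1), w_ser[1])           # inhibition grew
})
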