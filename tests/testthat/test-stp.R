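test_that("single spike from rest follows the facilitation-then-release order", {
  st <- stp_state(1)
  out <- step_stp(st, dt = 1e-4, pre_spikes = 1)
  ## u <- 0.2 + 0.2*(1-0.2) ~ 0.36 (relaxation over one 0.1-ms step is
  ## negligible), release 0.36, x <- 1 - 0.36
  expect_equal(out$state$u, 0.36, tolerance = 1e-3)
  expect_equal(out$release, 0.36, tolerance = 1e-3)
  expect_equal(out$state$x, 0.64, tolerance = 1e-3)
})

test_that("state relaxes to (U, 1) without spikes", {
  st <- stp_state(1)
  st$u <- 0.9; st$x <- 0.1
  out <- step_stp(st, dt = 10)  # >> both time constants
  expect_equal(out$state$u, 0.2, tolerance = 1e-4)
  expect_equal(out$state$x, 1, tolerance = 1e-4)
})

test_that("periodic-train release matches the event-map fixed point", {
  for (rate in c(5, 20, 45)) {
    oracle <- stp_fixed_point_iter(rate)
    closed <- stp_steady_state(rate)
    expect_equal(closed$release, oracle$release, tolerance = 1e-10)
    ## long-run simulation with step_stp at the same periodic train
    st <- stp_state(1)
    dt <- 1e-4
    period <- round(1 / (rate * dt))
    last_r <- NA
    for (k in seq_len(200 * period)) {
      out <- step_stp(st, dt, if (k %% period == 0) 1 else NULL)
      st <- out$state
      if (k %% period == 0) last_r <- out$release[1]
    }
    expect_equal(last_r, oracle$release, tolerance = 1e-3)
  }
})

test_that("u and x stay in bounds for arbitrary spike trains", {
  set.seed(3)
  st <- stp_state(5)
  for (k in 1:2000) {
    out <- step_stp(st, 1e-3, runif(5) < 0.2)
    st <- out$state
    expect_true(all(st$u >= 0 & st$u <= 1))
    expect_true(all(st$x >= 0 & st$x <= 1))
  }
})

test_that("mean release rate saturates sublinearly at high rates", {
  rates <- c(5, 20, 80)
  rel_rate <- vapply(rates, function(nu)
    nu * stp_steady_state(nu)$release, numeric(1))
  ## release rate grows, but slower than linearly
  expect_true(all(diff(rel_rate) > 0))
  gain <- rel_rate / rates
  expect_true(all(diff(gain) < 0))
  expect_lt(rel_rate[3] / rel_rate[1], rates[3] / rates[1] / 2)
})

test_that("invalid parameters are rejected", {
  expect_error(stp_state(1, U = 1.5), "\\[0, 1\\]")
  expect_error(stp_state(1, tau_d = 0), "positive")
})
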