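test_that("clock validates step and coarse interval", {
  ck <- sim_clock(1e-4, 1.2)
  expect_equal(ck$coarse_steps, 12000L)
  expect_error(sim_clock(0), "positive")
  expect_error(sim_clock(1e-4, 2.5e-4), "integer multiple")
})

test_that("trace decays exactly and zero is a fixed point", {
  tr <- trace_new(2, tau = 20e-3, value = c(0, 1))
  tr <- step_trace(tr, dt = 20e-3)
  expect_equal(tr$value[1], 0)
  expect_equal(tr$value[2], exp(-1), tolerance = 1e-12)
  expect_error(trace_new(1, tau = -1), "positive")
})

test_that("spikes increment the trace after decay", {
  tr <- trace_new(3, tau = 0.1, value = 1)
  tr <- step_trace(tr, dt = 0.05, spikes = c(1, 3))
  expect_equal(tr$value, exp(-0.5) + c(1, 0, 1), tolerance = 1e-12)
})

test_that("trace response is linear in the spike train", {
  set.seed(11)
  dt <- 1e-3
  for (rep in 1:5) {
    sa <- matrix(runif(200) < 0.1, 20)
    sb <- matrix(runif(200) < 0.2, 20)
    ta <- trace_new(20, 0.02); tb <- trace_new(20, 0.02)
    tc <- trace_new(20, 0.02)
    for (k in 1:10) {
      ta <- step_trace(ta, dt, sa[, k])
      tb <- step_trace(tb, dt, sb[, k])
      ## superposition: a train with both sets of spikes counts twice where
      ## both spike
      both <- c(which(sa[, k]), which(sb[, k]))
      tc <- step_trace(tc, dt, both)
    }
    expect_equal(tc$value, ta$value + tb$value, tolerance = 1e-12)
  }
})

test_that("long-run Poisson-driven trace mean approaches rate * tau", {
  set.seed(7)
  tau <- 0.05; rate <- 40; dt <- 1e-3
  tr <- trace_new(1, tau)
  acc <- 0; n <- 40000
  for (k in seq_len(n)) {
    tr <- step_trace(tr, dt, runif(1) < rate * dt)
    acc <- acc + tr$value
  }
  expect_equal(acc / n, rate * tau, tolerance = 0.1)
})
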