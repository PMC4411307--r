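test_that("self-coupled drift has roots 0, w_P/2, w_P with outer stability", {
  cp <- consolidation_params()
  fp <- consolidation_fixed_points(cp)
  expect_equal(fp$root, c(0, 0.25, 0.5), tolerance = 1e-9)
  expect_equal(fp$stable, c(TRUE, FALSE, TRUE))
})

test_that("with w clamped to wtilde the state converges to the nearest well", {
  cp <- consolidation_params()
  integrate_clamped <- function(w0, t_end = 30000) {
    wt <- w0
    for (k in seq_len(round(t_end / cp$interval)))
      wt <- step_reference_weights(wt, wt, cp)
    wt
  }
  expect_equal(integrate_clamped(0.4), 0.5, tolerance = 1e-6)
  expect_equal(integrate_clamped(0.26), 0.5, tolerance = 1e-6)
  expect_equal(integrate_clamped(0.1), 0, tolerance = 1e-6)
})

test_that("large clamped weight leaves a single elevated fixed point", {
  cp <- consolidation_params()
  fp <- consolidation_fixed_points(cp, w = 2)
  expect_equal(nrow(fp), 1L)
  expect_true(fp$stable)
  expect_gt(fp$root, cp$w_P)
})

test_that("reference weights move much more slowly than induction", {
  cp <- consolidation_params()
  ## largest drift magnitude at a typical operating point w - wtilde = 0.2
  rate <- abs(reference_weight_drift(0.5, 0.3, cp)) / cp$tau_cons
  expect_lt(rate, 1e-3)  # weight units per second
})

test_that("briefly induced changes revert without moving the set point", {
  cp <- consolidation_params()
  wt <- 0.5
  ## induce w = wt + 0.2 for 30 s (<< tau_cons), then revert
  for (k in 1:25) wt <- step_reference_weights(0.7, wt, cp)
  for (k in 1:200) wt <- step_reference_weights(0.5, wt, cp)
  expect_lt(abs(wt - 0.5), 0.005)  # set point unchanged to within 1%
})

test_that("parameter validation", {
  expect_error(consolidation_params(P = 0), "positive")
  expect_warning(consolidation_params(tau_cons = 60), "range")
})
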