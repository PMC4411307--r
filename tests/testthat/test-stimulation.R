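test_that("schedule respects burn-in and the configured interval means", {
  set.seed(1)
  expect_equal(nrow(schedule_stimuli(50, 4, burn_in = 50)), 0L)
  sch <- schedule_stimuli(3e4, 4, T_on = 1, T_off = 2, burn_in = 50)
  on_dur <- sch$t_end - sch$t_start
  off_dur <- sch$t_start[-1] - sch$t_end[-nrow(sch)]
  expect_lt(abs(mean(on_dur) - 1), 4 / sqrt(length(on_dur)))
  expect_lt(abs(mean(off_dur) - 2), 8 / sqrt(length(off_dur)))
  expect_true(min(sch$t_start) >= 50)
  expect_true(all(sch$pattern %in% 1:4))
  ## recall-phase switch: mean on-duration drops to 0.2 s
  phases <- data.frame(t_start = c(0, 1e4), T_on = c(1, 0.2),
                       T_off = c(2, 20))
  sch2 <- schedule_stimuli(6e4, 4, burn_in = 50, phases = phases)
  late <- sch2[sch2$t_start > 1e4, ]
  expect_lt(abs(mean(late$t_end - late$t_start) - 0.2),
            4 * 0.2 / sqrt(nrow(late)))
})

test_that("pattern_rate composes background and increment", {
  expect_equal(pattern_rate(c(0, 0.5, 1), active = FALSE), c(10, 10, 10))
  expect_equal(pattern_rate(c(0, 0.5, 1), active = TRUE), c(10, 27.5, 45))
  ## occlusion: masked units stay at background
  z <- c(1, 1, 1, 1); z[1:3] <- 0
  expect_equal(pattern_rate(z, TRUE), c(10, 10, 10, 45))
  expect_error(pattern_rate(2, TRUE), "\\[0, 1\\]")
})

test_that("shape patterns are binary, overlapping and seed-reproducible", {
  m1 <- make_shape_patterns(c(64, 64), 4, seed = 3)
  m2 <- make_shape_patterns(c(64, 64), 4, seed = 3)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% c(0, 1)))
  ov <- crossprod(m1)
  expect_true(all(ov[upper.tri(ov)] >= 1))
  ## single pattern is a non-empty connected-ish mask
  m <- make_shape_patterns(c(32, 32), 1, seed = 1)
  expect_gt(sum(m), 10)
})

test_that("Gaussian profiles peak at 1 and narrow with sigma", {
  z <- make_gaussian_profile_stimuli(1000, sigma = 50, n_profiles = 10,
                                     seed = 2)
  expect_equal(dim(z), c(1000L, 10L))
  expect_true(all(apply(z, 2, max) > 0.99))
  expect_true(all(z >= 0 & z <= 1))
  zn <- make_gaussian_profile_stimuli(1000, sigma = 0.4, n_profiles = 3,
                                      seed = 2)
  expect_true(all(colSums(zn > 0.01) <= 3))  # degenerate width
})
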