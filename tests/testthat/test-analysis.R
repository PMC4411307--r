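## synthetic raster helpers: planted ground truth, no simulation needed
make_poisson_raster <- function(n, rate, t_end, seed = 1) {
  set.seed(seed)
  counts <- rpois(n, rate * t_end)
  data.frame(time = runif(sum(counts), 0, t_end),
             id = rep(seq_len(n) - 1L, counts))
}

test_that("evoked rates recover planted stimulus-locked firing", {
  sch <- data.frame(pattern = rep(1:2, 10),
                    t_start = seq(0, 95, by = 5),
                    t_end = seq(0, 95, by = 5) + 2)
  ## neuron 0 fires only during pattern 1; neuron 1 is homogeneous 8 Hz
  on1 <- sch[sch$pattern == 1, ]
  t0 <- unlist(Map(function(a, b) seq(a + 0.01, b - 0.01, by = 0.05),
                   on1$t_start, on1$t_end))
  set.seed(2)
  t1 <- runif(800, 0, 100)
  raster <- data.frame(time = c(t0, t1),
                       id = c(rep(0L, length(t0)), rep(1L, length(t1))))
  nu <- evoked_rates(raster, sch, c(0, 100), n_neurons = 3)
  expect_gt(nu[1, 1], 15)
  expect_equal(nu[1, 2], 0)
  expect_equal(nu[2, 1], 8, tolerance = 0.25 * 8)
  expect_equal(nu[2, 2], 8, tolerance = 0.25 * 8)
  expect_equal(nu[3, ], c(0, 0))   # silent neuron
  ## zero on-time is flagged
  expect_warning(evoked_rates(raster, sch, c(0, 4), n_neurons = 2),
                 "zero on-time")
})

test_that("readout assignment recovers planted assemblies exactly", {
  ## 30 neurons, 3 patterns, planted membership 0-9, 10-19, 20-24;
  ## 25-29 reserve
  nu <- matrix(1, 30, 3)
  nu[1:10, 1] <- 30; nu[11:20, 2] <- 28; nu[21:25, 3] <- 35
  ro <- assign_readouts(nu)
  expect_equal(ro$members[[1]], 0:9)
  expect_equal(ro$members[[2]], 10:19)
  expect_equal(ro$members[[3]], 20:24)
  expect_equal(ro$reserve, 25:29)
  ## all-silent network: everyone in the reserve pool
  ro0 <- assign_readouts(matrix(0, 10, 2))
  expect_true(all(lengths(ro0$members) == 0))
  expect_equal(ro0$reserve, 0:9)
  ## infinite threshold empties the sets
  roInf <- assign_readouts(nu, threshold = Inf)
  expect_true(all(lengths(roInf$members) == 0))
})

test_that("population activity has the documented normalisation", {
  ## n members firing once in one 50-ms bin -> 20 Hz in that bin
  raster <- data.frame(time = rep(0.125, 8), id = 0:7)
  pa <- population_activity(raster, members = 0:7, bin = 0.05,
                            t_range = c(0, 0.2))
  expect_equal(pa$rate[3], 20)
  expect_equal(pa$rate[-3], rep(0, 3))
  expect_error(population_activity(raster, integer(0)), "empty")
  ## stationary Poisson members give a flat series at the rate
  r2 <- make_poisson_raster(20, 15, 50, seed = 4)
  pa2 <- population_activity(r2, 0:19, bin = 1, t_range = c(0, 50))
  expect_equal(mean(pa2$rate), 15, tolerance = 0.5)
})

test_that("evoked covariance is a centred Gram matrix", {
  ## orthogonal zero-mean response vectors -> diagonal covariance
  nu <- cbind(c(1, -1, 1, -1, 0, 0), c(0, 0, 0, 0, 3, -3))
  C <- evoked_covariance(nu)
  expect_equal(C[1, 2], 0)
  expect_true(isSymmetric(C))
  expect_true(all(eigen(C)$values > -1e-12))
  ## identical responses for two stimuli: equal diagonal and off-diagonal
  nu2 <- cbind(rnorm(50), 0)
  nu2[, 2] <- nu2[, 1]
  C2 <- evoked_covariance(nu2)
  expect_equal(C2[1, 1], C2[1, 2], tolerance = 1e-12)
})

test_that("CV-ISI separates regular, Poisson and gamma firing", {
  reg <- data.frame(time = seq(0.1, 60, by = 0.1), id = 0L)
  set.seed(6)
  pois <- data.frame(time = cumsum(rexp(600, 10)), id = 1L)
  gam <- data.frame(time = cumsum(rgamma(600, shape = 2, rate = 20)),
                    id = 2L)
  raster <- rbind(reg, pois, gam)
  st <- spike_stats(raster, c(0, 55), n_neurons = 4)
  expect_equal(st$cv[1], 0, tolerance = 1e-10)
  expect_equal(st$cv[2], 1, tolerance = 0.15)
  expect_equal(st$cv[3], 1 / sqrt(2), tolerance = 0.1)
  expect_true(is.na(st$cv[4]))
  expect_equal(st$n_excluded, 1L)
  expect_equal(st$rate[1], 10, tolerance = 0.01)
})

test_that("PSTH recovers a planted rate step", {
  events <- seq(10, 190, by = 10)
  set.seed(8)
  ## 5 neurons at 2 Hz baseline, 40 Hz in the 100 ms after each event
  base <- make_poisson_raster(5, 2, 200, seed = 8)
  extra <- do.call(rbind, lapply(events, function(e) {
    n <- rpois(1, 5 * 38 * 0.1)
    data.frame(time = runif(n, e, e + 0.1), id = sample(0:4, n, TRUE))
  }))
  raster <- rbind(base, extra)
  ps <- psth(raster, events, members = 0:4, window = c(-0.2, 0.3),
             bin = 0.05)
  pre <- mean(ps$rate[ps$t < 0])
  during <- mean(ps$rate[ps$t > 0 & ps$t < 0.1])
  expect_equal(pre, 2, tolerance = 1)
  expect_equal(during, 40, tolerance = 5)
  ## empty raster gives a zero PSTH
  ps0 <- psth(data.frame(time = numeric(0), id = integer(0)), events,
              members = 0:4)
  expect_true(all(ps0$rate == 0))
})
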