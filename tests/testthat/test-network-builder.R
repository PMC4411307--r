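test_that("recurrent wiring matches the binomial expectation, no self loops", {
  spec <- network_spec(n_exc = 400, n_inh = 100, p_rec = 0.1,
                       input = list(mode = "sparse", n_input = 400,
                                    p = 0.05))
  net <- build_network(spec, seed = 2)
  ee <- net$edges$e_e
  expect_false(any(ee$pre == ee$post))
  n_exp <- 0.1 * 400 * 399
  expect_lt(abs(length(ee$pre) - n_exp) / sqrt(n_exp * 0.9), 5)
  ii <- net$edges$i_i
  expect_false(any(ii$pre == ii$post))
  ## every excitatory neuron has at least one afferent
  expect_equal(length(unique(net$edges$input_e$post)), 400L)
  ## p_rec = 0 gives no recurrent synapses
  net0 <- build_network(network_spec(50, 10, p_rec = 0,
                                     input = list(mode = "sparse",
                                                  n_input = 50, p = 0.2)),
                        seed = 1)
  expect_equal(length(net0$edges$e_e$pre), 0L)
})

test_that("receptive-field afferents lie within the disc radius", {
  spec <- network_spec(n_exc = 60, n_inh = 15,
                       input = list(mode = "rf", grid = c(64, 64),
                                    radius = 8))
  net <- build_network(spec, seed = 4)
  ie <- net$edges$input_e
  xs <- (ie$pre %% 64) + 1
  ys <- (ie$pre %/% 64) + 1
  cx <- net$rf_centres[ie$post + 1, "x"]
  cy <- net$rf_centres[ie$post + 1, "y"]
  expect_true(all((xs - cx)^2 + (ys - cy)^2 <= 8^2 + 1e-9))
  ## an infeasible radius is rejected
  expect_error(network_spec(10, 2, input = list(mode = "rf",
                                                grid = c(10, 10),
                                                radius = 8)), "radius")
})

test_that("wiring is deterministic under the seed and scale-invariant", {
  spec <- network_spec(200, 50, input = list(mode = "sparse",
                                             n_input = 200, p = 0.05))
  n1 <- build_network(spec, seed = 7)
  n2 <- build_network(spec, seed = 7)
  expect_identical(n1$edges, n2$edges)
  ## in-degree / N constant across scales (within sampling error)
  deg <- function(n) length(n$edges$e_e$pre) / n$n_exc / n$n_exc
  big <- build_network(network_spec(400, 100,
                                    input = list(mode = "sparse",
                                                 n_input = 400, p = 0.05)),
                       seed = 7)
  expect_lt(abs(deg(n1) - deg(big)), 0.005)
})

test_that("embed_assembly elevates exactly the intra-assembly synapses", {
  spec <- network_spec(300, 75, p_rec = 0.1,
                       input = list(mode = "sparse", n_input = 300,
                                    p = 0.05))
  net <- build_network(spec, seed = 5)
  members <- 0:49
  net2 <- embed_assembly(net, members, w_strong = 0.9)
  ee <- net2$edges$e_e
  inside <- ee$pre %in% members & ee$post %in% members
  expect_true(all(ee$w[inside] == 0.9))
  expect_true(all(ee$w[!inside] == net$edges$e_e$w[!inside]))
  n_exp <- 0.1 * 50 * 49
  expect_lt(abs(sum(inside) - n_exp) / sqrt(n_exp), 5)
  ## empty member set and unknown ids
  expect_identical(embed_assembly(net, integer(0), 2), net)
  expect_error(embed_assembly(net, c(0, 500), 2), "unknown")
})
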