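test_that("output_side chains valid-convolution and pooling arithmetic", {
  expect_equal(output_side(28, 5, 1), 24L)
  expect_equal(output_side(24, 2, 2, "pool"), 12L)
  expect_equal(output_side(12, 5, 1), 8L)
  expect_equal(output_side(8, 2, 2, "pool"), 4L)
  expect_error(output_side(4, 5, 1), "smaller than the kernel")
  expect_error(output_side(9, 2, 2, "pool"), "divide")
})

test_that("network_config resolves shapes and rejects bad stacks", {
  cfg <- full_network_config()
  sides <- vapply(cfg$layers, `[[`, integer(1), "out_side")
  expect_equal(sides, c(24L, 12L, 8L, 4L, 1L))
  expect_error(network_config(12, list(layer_spec("conv", maps = 2))),
               "fully connected")
  expect_error(layer_spec("conv", maps = 0), "positive")
  expect_error(layer_spec("fc", maps = 10, t_learn = -1), "positive")
})

test_that("adjustable synapse counts follow the shared-kernel arithmetic", {
  expect_equal(count_adjustable_synapses(full_network_config(16, 32, 1000)),
               5^2 * 1 * 16 + 5^2 * 16 * 32 + 4^2 * 32 * 1000)
  expect_equal(count_adjustable_synapses(full_network_config(16, 32, 1000)),
               525200)
})

test_that("learning inhibition targets match brute-force enumeration", {
  # 8x8 grid, 4 maps, radius 2 (12x12 input through a 5x5 kernel)
  cfg <- network_config(12, list(
    layer_spec("conv", maps = 4, kernel = 5, r_inh_learn = 2),
    layer_spec("pool"),
    layer_spec("fc", maps = 5)))
  net <- build_network(cfg, seed = 1)

  for (pos in list(c(5, 5), c(1, 1), c(8, 3))) {
    got <- inhibition_targets_learning(net, 1, map = 2, row = pos[1], col = pos[2])
    want <- brute_learning_targets(4, 8, 2, 2, pos[1], pos[2])
    expect_equal(as.matrix(got), want, ignore_attr = TRUE)
  }
  # interior position: 63 intra-map + 3 * 25 inter-map targets
  expect_equal(nrow(inhibition_targets_learning(net, 1, 1, 5, 5)), 63 + 3 * 25)
  # corner: the inter-map window clips to 3x3 per other map
  expect_equal(nrow(inhibition_targets_learning(net, 1, 1, 1, 1)), 63 + 3 * 9)
  # fully connected: all other neurons
  expect_equal(nrow(inhibition_targets_learning(net, 3, map = 2)), 4)
})

test_that("inference inhibition is inter-map only and configurable", {
  cfg <- network_config(12, list(
    layer_spec("conv", maps = 4, kernel = 5, r_inh_infer = 0),
    layer_spec("pool"),
    layer_spec("fc", maps = 5)))
  net <- build_network(cfg, seed = 1)
  got <- inhibition_targets_inference(net, 1, map = 2, row = 3, col = 3)
  expect_equal(nrow(got), 3)                      # same position, other maps
  expect_false(any(got$map == 2))                 # own map never targeted
  expect_true(all(got$row == 3 & got$col == 3))

  net$layers[[1]]$r_inh_infer <- -1L              # disabled
  expect_equal(nrow(inhibition_targets_inference(net, 1, 2, 3, 3)), 0)
  expect_equal(nrow(inhibition_targets_inference(net, 3, 1)), 0)  # fc: none
})

test_that("pooling relays with floor-divided coordinates", {
  expect_equal(pool_route(6, 5), c(3L, 3L))
  expect_equal(pool_route(1, 1), c(1L, 1L))
  expect_equal(pool_route(2, 3), c(1L, 2L))
})

test_that("pooling relays every spike in a window (no gating)", {
  # two spikes landing in the same pooling window are both relayed
  cfg <- network_config(6, list(
    layer_spec("conv", maps = 1, kernel = 3, t_learn = 99, t_infer = 1,
               init_mean = 1, init_sd = 0),
    layer_spec("pool"),
    layer_spec("fc", maps = 2, t_learn = 1e6, t_infer = 1e6)))
  net <- build_network(cfg)
  ev <- spike_events(time = c(1, 2), row = c(1, 2), col = c(1, 2))
  rec <- run_stream(ev, net, plastic = FALSE)
  pool_sp <- rec$spikes[rec$spikes$layer == 2, ]
  conv_sp <- rec$spikes[rec$spikes$layer == 1, ]
  expect_equal(nrow(pool_sp), nrow(conv_sp))
  expect_gt(nrow(pool_sp), 0)
})

test_that("build_network draws clipped normal weights deterministically", {
  cfg <- toy_network_config()
  n1 <- build_network(cfg, seed = 7)
  n2 <- build_network(cfg, seed = 7)
  expect_identical(n1$layers[[1]]$w, n2$layers[[1]]$w)
  expect_identical(n1$layers[[3]]$w, n2$layers[[3]]$w)
  expect_true(all(n1$layers[[1]]$w >= 0 & n1$layers[[1]]$w <= 1))
  expect_equal(mean(n1$layers[[1]]$w), 0.8, tolerance = 0.1)
  expect_equal(mean(n1$layers[[3]]$w), 0.67, tolerance = 0.05)

  cfg0 <- network_config(12, list(
    layer_spec("conv", maps = 2, init_mean = 0.8, init_sd = 0),
    layer_spec("pool"),
    layer_spec("fc", maps = 3, init_mean = 0.5, init_sd = 0)))
  n0 <- build_network(cfg0)
  expect_true(all(n0$layers[[1]]$w == 0.8))
  expect_true(all(n0$layers[[3]]$w == 0.5))
})

test_that("a learning crossing updates only the winning map's shared kernel", {
  cfg <- network_config(6, list(
    layer_spec("conv", maps = 2, kernel = 3, t_learn = 2, t_infer = 1e6,
               init_mean = 0.5, init_sd = 0,
               stdp = stdp_params(0.1, -0.02)),
    layer_spec("pool"),
    layer_spec("fc", maps = 2, t_learn = 1e6, t_infer = 1e6)))
  net <- build_network(cfg)
  # bias map 1 so it wins the learning competition
  net$layers[[1]]$w[, , , 1] <- 0.9
  ev <- spike_events(time = c(1, 2, 3), row = 2, col = 2)
  rec <- run_stream(ev, net, plastic = TRUE)
  expect_gt(rec$counters$pseudo_spikes[1], 0)
  expect_false(identical(rec$network$layers[[1]]$w[, , , 1],
                         net$layers[[1]]$w[, , , 1]))
  expect_identical(rec$network$layers[[1]]$w[, , , 2],
                   net$layers[[1]]$w[, , , 2])
})

test_that("disabling inter-map learning inhibition collapses the maps", {
  run_kernels <- function(r) {
    cfg <- toy_network_config()
    cfg$layers[[1]]$r_inh_learn <- r
    set.seed(7)
    toy <- generate_toy_set(toy_task_spec())
    net <- train_once(make_stream(toy$train, toy_encoder_params()),
                      build_network(cfg))$network
    k <- net$layers[[1]]$w
    mean(as.vector(dist(t(sapply(1:4, function(m) as.vector(k[, , 1, m]))))))
  }
  expect_gt(run_kernels(2L), 10 * run_kernels(-1L))
})

test_that("network checkpoints round-trip through JSON", {
  net <- build_network(toy_network_config(), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$input_side, net$input_side)
  expect_equal(back$layers[[1]]$w, net$layers[[1]]$w)
  expect_equal(back$layers[[3]]$w, net$layers[[3]]$w)
  expect_equal(back$layers[[1]]$stdp$alpha_plus, 0.03)
})

test_that("tidy() exposes one row per adjustable weight", {
  net <- build_network(toy_network_config(), seed = 2)
  td <- tidy(net)
  expect_equal(nrow(td),
               count_adjustable_synapses(net$config))
  expect_true(all(td$weight >= 0 & td$weight <= 1))
  # spot-check alignment for the fc layer
  expect_equal(td$weight[td$layer == 3 & td$map == 1 & td$in_map == 1 &
                           td$kx == 1 & td$ky == 2],
               net$layers[[3]]$w[2, 1])
})
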