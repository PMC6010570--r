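test_that("an empty stream leaves the network untouched", {
  net <- build_network(toy_network_config(), seed = 5)
  empty <- structure(list(
    events = spike_events(time = double(), row = integer(), col = integer()),
    log = tibble::tibble(stimulus = integer(), label = integer(),
                         t_start = double(), duration = double())),
    class = "spike_stream")
  fit <- train_once(empty, net)
  expect_identical(fit$network$layers[[1]]$w, net$layers[[1]]$w)
  expect_identical(fit$network$layers[[3]]$w, net$layers[[3]]$w)
})

test_that("an untrained random network classifies far below a trained one", {
  set.seed(42)
  toy <- generate_toy_set(toy_task_spec(n_train = 120, n_test = 60))
  net <- build_network(toy_network_config())
  ev <- evaluate_network(net,
                         make_stream(toy$train, toy_encoder_params()),
                         make_stream(toy$test, toy_encoder_params()))
  # labeling random features is somewhat better than the 25% chance floor
  # (the tally itself extracts information), but nowhere near trained
  expect_gt(ev$accuracy, 0.1)
  expect_lt(ev$accuracy, 0.6)
})

test_that("a hand-built one-neuron-per-class network is perfect on clean data", {
  spec <- toy_task_spec(noise_sd = 0, jitter = 0, n_train = 20, n_test = 20)
  set.seed(2)
  toy <- generate_toy_set(spec)
  cfg <- network_config(12, list(
    layer_spec("fc", maps = 4, t_learn = 1e6, t_infer = 5,
               init_mean = 0, init_sd = 0)))
  net <- build_network(cfg)
  # fc rows are (map, row, col) with col fastest and a single input map, so
  # a prototype maps onto a weight column via its transpose
  for (k in 1:4) net$layers[[1]]$w[, k] <- as.vector(t(toy$prototypes[[k]]))
  ev <- evaluate_network(net,
                         make_stream(toy$train, toy_encoder_params()),
                         make_stream(toy$test, toy_encoder_params()))
  expect_equal(ev$accuracy, 1)
})

test_that("frozen evaluation is deterministic given the same streams", {
  res <- toy_run_cached()
  st <- make_stream(res$toy$test[1:10, ], toy_encoder_params())
  a <- run_stream(st, res$fit$network, plastic = FALSE)
  b <- run_stream(st, res$fit$network, plastic = FALSE)
  expect_identical(a$spikes, b$spikes)
})

test_that("the online running error falls below 10% within the training pass", {
  res <- toy_run_cached()
  m <- res$fit$metrics
  expect_lt(tail(m$running_error, 1), 0.10)
  # late-pass performance beats the cold start
  expect_lt(mean(!m$correct[301:400]), mean(!m$correct[1:100]))
})

test_that("training counters respect the online constraints", {
  res <- toy_run_cached()
  expect_equal(res$fit$record$boundary_resets, 0)
  expect_false(res$fit$settings$reset_per_example)
  expect_false(res$fit$settings$layerwise)
  g <- glance(res$fit)
  expect_equal(g$n_stimuli, 400L)
  expect_s3_class(autoplot(res$fit), "ggplot")
  expect_s3_class(autoplot(res$eval), "ggplot")
})

test_that("inter-map inference inhibition contributes to the readout", {
  base <- toy_run_cached()$eval$accuracy
  cfg <- toy_network_config()
  cfg$layers[[1]]$r_inh_infer <- -1L   # disabled outright
  off <- run_toy_experiment(seed = 1, config = cfg)$eval$accuracy
  expect_lt(off, base - 0.1)
})

test_that("presentation-time sweep modes coincide at factor one", {
  sw <- presentation_time_sweep(factors = 1, seed = 3,
                                spec = toy_task_spec(n_train = 150,
                                                     n_test = 40))
  expect_equal(nrow(sw), 2)
  expect_equal(sw$accuracy[sw$mode == "matched"],
               sw$accuracy[sw$mode == "fixed"])
})

test_that("accuracy is stable across learning-rate magnitudes but not near zero", {
  sw <- learning_rate_sweep(c(0.002, 0.5, 2), seed = 3)
  stable <- sw[sw$multiplier >= 0.5, ]
  expect_lt(max(stable$test_accuracy) - min(stable$test_accuracy), 0.05)
  # a near-zero rate does not converge within one pass
  expect_lt(sw$test_accuracy[sw$multiplier == 0.002],
            min(stable$test_accuracy) - 0.1)
})

test_that("YAML run configurations map onto network and encoder parameters", {
  skip_if_not_installed("yaml")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "input_side: 12",
    "layers:",
    "  - kind: conv",
    "    maps: 4",
    "    kernel: 3",
    "    t_learn: 6",
    "    t_infer: 3",
    "    stdp: {alpha_plus: 0.03, alpha_minus: -0.00375}",
    "  - kind: pool",
    "  - kind: fc",
    "    maps: 20",
    "    t_learn: 20",
    "encoder: {duration: 2}"), f)
  rc <- read_run_config(f)
  expect_s3_class(rc$config, "network_config")
  expect_equal(rc$config$layers[[1]]$t_learn, 6)
  expect_equal(rc$config$layers[[3]]$maps, 20)
  expect_equal(rc$encoder$duration, 2)
})
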