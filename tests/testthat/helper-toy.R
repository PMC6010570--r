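# Shared fixtures: expensive toy-protocol runs are computed once per test
# session and reused across test files.

.toy_memo <- new.env(parent = emptyenv())

toy_run_cached <- function(name = "default", ...) {
  if (is.null(.toy_memo[[name]]))
    .toy_memo[[name]] <- run_toy_experiment(seed = 1, ...)
  .toy_memo[[name]]
}

# class-conditional mean images of a generated toy set
toy_class_means <- function(toy) {
  lapply(sort(unique(toy$train$label)), function(k) {
    imgs <- toy$train$image[toy$train$label == k]
    Reduce(`+`, imgs) / length(imgs)
  })
}

# best preferred-feature/class-mean correlation per class
feature_class_correlations <- function(res) {
  net <- res$fit$network
  cms <- toy_class_means(res$toy)
  tally <- res$eval$tally
  vapply(seq_along(cms), function(k) {
    ns <- which(tally$preferred == k)
    if (length(ns) == 0) return(NA_real_)
    max(vapply(ns, function(n)
      cor(as.vector(preferred_feature(net, 3, n)), as.vector(cms[[k]])),
      numeric(1)))
  }, numeric(1))
}

# small random network + stream for kernel property tests
random_small_case <- function(seed, input_side = 6, n_events = 250,
                              integer_times = FALSE) {
  set.seed(seed)
  cfg <- network_config(input_side, list(
    layer_spec("conv", maps = 2, kernel = 3,
               t_learn = sample(2:4, 1), t_infer = sample(2:3, 1),
               r_inh_learn = sample(0:2, 1), r_inh_infer = 0,
               stdp = stdp_params(0.1, -0.02)),
    layer_spec("pool"),
    layer_spec("fc", maps = 4, t_learn = 4, t_infer = 3,
               stdp = stdp_params(0.1, -0.02))))
  net <- build_network(cfg, seed = seed + 1000)
  times <- if (integer_times) sort(sample(0:60, n_events, replace = TRUE))
           else sort(runif(n_events, 0, 60))
  ev <- spike_events(time = times,
                     row = sample(seq_len(input_side), n_events, TRUE),
                     col = sample(seq_len(input_side), n_events, TRUE))
  list(net = net, events = ev)
}

# brute-force enumeration of learning-inhibition targets, written
# independently of the package implementation
brute_learning_targets <- function(maps, side, r, map, row, col) {
  out <- NULL
  for (m in seq_len(maps)) {
    for (x in seq_len(side)) {
      for (y in seq_len(side)) {
        if (m == map && x == row && y == col) next
        hit <- if (m == map) TRUE
               else (abs(x - row) <= r && abs(y - col) <= r)
        if (hit) out <- rbind(out, c(m, x, y))
      }
    }
  }
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}
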