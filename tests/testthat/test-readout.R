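test_that("the labeling pass credits exactly the strongest neuron per stimulus", {
  resp <- rbind(c(5, 2, 0),   # neuron 1 wins, class 3
                c(4, 4, 0),   # tie: lowest index credited
                c(0, 0, 0),   # silent: no increment
                c(0, 1, 7))   # neuron 3 wins, class 1
  tal <- tally_labeling_pass(resp, labels = c(3, 1, 2, 1))
  expect_equal(unname(tal$counts[1, "3"]), 1L)
  expect_equal(unname(tal$counts[1, "1"]), 1L)
  expect_equal(unname(tal$counts[3, "1"]), 1L)
  expect_equal(sum(tal$counts), 3L)
  expect_equal(tal$n_silent, 1L)
  expect_equal(tal$preferred, c(1, NA, 1))  # ties to the lowest class index
})

test_that("classification follows the max-response neuron with labeled fallback", {
  tal <- tally_labeling_pass(rbind(c(9, 0, 0), c(0, 9, 0)), labels = c(4, 7))
  # three neurons, only 1 and 2 labeled
  tal3 <- tally_labeling_pass(rbind(c(9, 0, 0), c(0, 9, 0)), labels = c(4, 7))
  expect_equal(classify_responses(c(1, 5, 0), tal3), 7)
  # unlabeled max neuron: fall back to the strongest labeled one
  expect_equal(classify_responses(c(2, 1, 10), tal3), 4)
  # all-zero response abstains and counts as incorrect
  pred <- classify_responses(rbind(c(0, 0, 0), c(3, 0, 0)), tal3)
  expect_true(is.na(pred[1]))
  expect_equal(pred[2], 4)
  expect_equal(classification_accuracy(pred, c(4, 4)), 0.5)
  # an empty tally is an error
  empty <- tally_labeling_pass(matrix(0, 2, 3), labels = c(1, 2))
  expect_error(classify_responses(c(1, 0, 0), empty), "no labeled neuron")
})

test_that("the label-efficiency curve reproduces the full tally at fraction 1", {
  set.seed(4)
  n <- 60
  labels <- sample(1:3, n, replace = TRUE)
  resp <- t(sapply(labels, function(k) {
    r <- rpois(6, 1); r[k * 2 - 1] <- r[k * 2 - 1] + 6; r
  }))
  test_labels <- sample(1:3, 30, replace = TRUE)
  test_resp <- t(sapply(test_labels, function(k) {
    r <- rpois(6, 1); r[k * 2 - 1] <- r[k * 2 - 1] + 6; r
  }))
  curve <- label_efficiency_curve(resp, labels, test_resp, test_labels,
                                  fractions = c(0.05, 0.5, 1), seed = 1)
  full <- classification_accuracy(
    classify_responses(test_resp, tally_labeling_pass(resp, labels)),
    test_labels)
  expect_equal(curve$accuracy[curve$fraction == 1], full)
  expect_equal(curve$n_labels, c(3, 30, 60))
  curve2 <- label_efficiency_curve(resp, labels, test_resp, test_labels,
                                   fractions = c(0.05, 0.5, 1), seed = 1)
  expect_identical(curve, curve2)
  expect_error(label_efficiency_curve(resp, labels, test_resp, test_labels,
                                      fractions = 0), "\\(0, 1\\]")
})

test_that("online running error tallies labels on the fly", {
  # neuron k responds to class k; first occurrence of each class must fail
  # (cold start), later ones succeed
  labels <- c(1, 1, 2, 2, 1, 2)
  resp <- rbind(c(5, 0), c(5, 0), c(0, 5), c(0, 5), c(5, 0), c(0, 5))
  m <- online_running_error(resp, labels, window = 3)
  expect_equal(m$correct, c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(m$running_error[1], 1)
  expect_equal(m$running_error[6], 0)          # last 3 all correct
  expect_equal(m$running_error[4], 1 / 3)      # window = stimuli 2..4
})

test_that("first-layer preferred features are the kernels themselves", {
  net <- build_network(toy_network_config(), seed = 2)
  expect_identical(preferred_feature(net, 1, 3), net$layers[[1]]$w[, , 1, 3])
})

test_that("a one-hot second-stage kernel tiles the selected first-stage kernel", {
  cfg <- network_config(14, list(
    layer_spec("conv", maps = 2, kernel = 3),
    layer_spec("pool"),
    layer_spec("conv", maps = 1, kernel = 3),
    layer_spec("pool"),
    layer_spec("fc", maps = 2)))
  net <- build_network(cfg, seed = 1)
  net$layers[[3]]$w[, , 1, 1] <- 0   # never select map 1
  net$layers[[3]]$w[, , 2, 1] <- 1   # one-hot on map 2, weight 1 everywhere
  pf <- preferred_feature(net, 3, 1)
  k2 <- net$layers[[1]]$w[, , 1, 2]
  # independent composition oracle: place the map-2 kernel at every pre-pool
  # anchor of every kernel position, averaging overlaps
  side <- (3 * 2 - 1) + 3
  canvas <- matrix(0, side, side); count <- matrix(0, side, side)
  for (x in 0:2) for (y in 0:2) for (jx in 0:1) for (jy in 0:1) {
    rows <- (2 * x + jx) + 1:3; cols <- (2 * y + jy) + 1:3
    canvas[rows, cols] <- canvas[rows, cols] + k2
    count[rows, cols] <- count[rows, cols] + 1
  }
  expect_equal(pf, canvas / pmax(count, 1))
})

test_that("response matrices count top-layer spikes inside stimulus windows", {
  res <- toy_run_cached()
  rec <- res$fit$record
  resp <- response_matrix(rec, res$fit$log)
  expect_equal(dim(resp), c(400, 20))
  expect_equal(sum(resp),
               sum(rec$spikes$layer == 3))
  long <- stimulus_responses(rec, res$fit$log)
  expect_equal(sum(long$spikes), sum(resp))
})
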