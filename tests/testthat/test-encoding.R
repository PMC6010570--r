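test_that("zero-intensity pixels emit nothing", {
  img <- matrix(0, 5, 5)
  ev <- encode_image(img, encoder_params())
  expect_equal(nrow(ev), 0)
  img[2, 2] <- 0.5
  set.seed(1)
  ev <- encode_image(img, encoder_params())
  expect_true(all(ev$row == 2 & ev$col == 2))
  expect_error(encode_image(matrix(1.5, 2, 2)), "\\[0, 1\\]")
})

test_that("a noiseless full-intensity pixel fires exactly periodically", {
  p <- encoder_params(base_period = 0.1, rate_jitter_sd = 0, isi_jitter = FALSE,
                      duration = 1)
  img <- matrix(0, 3, 3); img[1, 1] <- 1
  ev <- encode_image(img, p, t0 = 5)
  expect_equal(nrow(ev), 10)                      # duration / base_period
  expect_equal(ev$time, 5 + 0.1 * (0:9))
  # half intensity: half the rate
  img[1, 1] <- 0.5
  expect_equal(nrow(encode_image(img, p)), 5)
})

test_that("the uniform inter-spike-interval jitter doubles the mean rate", {
  p <- encoder_params(base_period = 0.1, rate_jitter_sd = 0, isi_jitter = TRUE,
                      duration = 4)
  img <- matrix(0, 2, 2); img[1, 1] <- 1
  set.seed(42)
  counts <- replicate(300, nrow(encode_image(img, p)))
  # Monte-Carlo oracle: mean ISI is halved, so ~ 2 * duration / base_period
  expect_equal(mean(counts), 2 * 4 / 0.1, tolerance = 0.05)
})

test_that("event times stay inside the stimulus window and increase per pixel", {
  set.seed(8)
  img <- matrix(runif(36), 6, 6)
  for (i in 1:5) {
    ev <- encode_image(img, encoder_params(duration = 1.3), t0 = 2)
    expect_true(all(ev$time >= 2 & ev$time < 3.3))
    per_px <- split(ev$time, paste(ev$row, ev$col))
    expect_true(all(vapply(per_px, function(tt) all(diff(tt) > 0), logical(1))))
  }
})

test_that("make_stream concatenates stimuli back-to-back with a separate log", {
  set.seed(3)
  imgs <- list(matrix(runif(16), 4, 4), matrix(runif(16), 4, 4))
  p <- encoder_params(duration = 1)
  st <- make_stream(imgs, p, labels = c(1, 2), duration_factors = c(1, 2))
  expect_equal(st$log$t_start, c(0, 1))
  expect_equal(st$log$duration, c(1, 2))
  ev2 <- st$events[st$events$time >= 1, ]
  expect_true(all(ev2$time < 3))
  # no marker columns beyond the address-event format
  expect_named(st$events, c("time", "layer", "map", "row", "col", "kind"))
})

test_that("random duration factors keep the mean total duration unscaled", {
  set.seed(1)
  f <- runif(2000, 0.1, 1.9)
  expect_equal(mean(f), 1, tolerance = 0.05)
})

test_that("encoding is reproducible under a fixed seed", {
  img <- matrix(runif(25), 5, 5)
  set.seed(99); a <- encode_image(img, encoder_params())
  set.seed(99); b <- encode_image(img, encoder_params())
  expect_identical(a, b)
})

test_that("28x28 digit-like stimuli emit 1,400-3,500 events at the default encoder", {
  set.seed(21)
  toy <- generate_toy_set(toy_task_spec(side = 28, n_train = 40, n_test = 4))
  st <- make_stream(toy$train, encoder_params(duration = 1))
  brk <- c(st$log$t_start, max(st$log$t_start) + 1)
  counts <- table(cut(st$events$time, brk, right = FALSE))
  expect_true(all(counts >= 1400 & counts <= 3500))
})

test_that("IDX image and label files round-trip", {
  set.seed(5)
  imgs <- lapply(1:3, function(i) matrix(round(runif(49) * 255) / 255, 7, 7))
  labs <- c(0L, 3L, 9L)
  fi <- withr::local_tempfile(); fl <- withr::local_tempfile()
  write_idx_images(imgs, fi)
  write_idx_labels(labs, fl)
  expect_equal(read_idx_images(fi), imgs)
  expect_equal(read_idx_labels(fl), labs)
  # wrong magic number
  expect_error(read_idx_images(fl), "magic")
  expect_error(read_idx_labels(fi), "magic")
  # truncation
  writeBin(readBin(fi, "raw", 20), fi)
  expect_error(read_idx_images(fi), "truncated")
})

test_that("PGM images round-trip (ASCII) and binary P5 files are readable", {
  img <- matrix(round(runif(30) * 255) / 255, 5, 6)
  f <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(img, f)
  expect_equal(read_pgm(f), img, tolerance = 1 / 255)
  # raw P5 variant written by hand
  f5 <- withr::local_tempfile(fileext = ".pgm")
  con <- file(f5, "wb")
  writeChar("P5\n6 5\n255\n", con, eos = NULL)
  writeBin(as.integer(round(t(img) * 255)), con, size = 1)
  close(con)
  expect_equal(read_pgm(f5), img, tolerance = 1 / 255)
  expect_error(read_pgm(withr::local_tempfile(fileext = ".txt") |>
                          (\(p) { writeLines("P6 junk", p); p })()),
               "PGM")
})
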