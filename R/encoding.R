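#' Rate-encoder parameters
#'
#' Grayscale images are converted to noisy periodic spike trains whose mean
#' firing rate is proportional to pixel intensity: a full-intensity pixel
#' fires once per `base_period`. Two noise sources randomize the trains:
#' each pixel's mean rate is drawn from a Gaussian centred on its nominal
#' rate (relative standard deviation `rate_jitter_sd`, negative draws
#' clipped to zero), and, when `isi_jitter` is on, every inter-spike
#' interval is additionally multiplied by a uniform `[0, 1]` number — which
#' doubles the mean rate.
#'
#' With the defaults (`base_period = 0.12`, `duration = 1`, jitter on) a
#' 28x28 digit-like image with a typical intensity mass (around 120 in
#' summed pixel values) emits roughly 2,000 events per presentation, within
#' the 1,400–3,500 band the method assumes. Only the spike generator knows
#' this timescale; the network consumes relative timing alone.
#'
#' @param base_period Time per spike for a full-intensity pixel.
#' @param rate_jitter_sd Relative standard deviation of the per-pixel rate
#'   Gaussian (0 disables).
#' @param isi_jitter Multiply each inter-spike interval by uniform `[0, 1]`?
#' @param duration Presentation time per stimulus.
#' @return An `encoder_params` object.
#' @export
encoder_params <- function(base_period = 0.12, rate_jitter_sd = 0.1,
                           isi_jitter = TRUE, duration = 1) {
  if (base_period <= 0 || duration <= 0)
    abort("`base_period` and `duration` must be positive")
  if (rate_jitter_sd < 0) abort("`rate_jitter_sd` must be non-negative")
  structure(list(base_period = base_period, rate_jitter_sd = rate_jitter_sd,
                 isi_jitter = isTRUE(isi_jitter), duration = duration),
            class = "encoder_params")
}

#' Encode a grayscale image as a spike-event stream
#'
#' Per pixel with intensity `v > 0`: the mean rate is `v / base_period`
#' (Gaussian-perturbed, clipped at zero), the first spike falls at `t0`, and
#' subsequent spikes follow after (optionally jittered) inter-spike
#' intervals until the presentation `duration` is exhausted. Zero-intensity
#' pixels emit nothing; all event times lie in `[t0, t0 + duration)` and are
#' strictly increasing per pixel.
#'
#' @param img Matrix of intensities in `[0, 1]`.
#' @param params An [encoder_params()] object. `duration` may be overridden
#'   per call via `duration`.
#' @param t0 Stream offset of this stimulus.
#' @param duration Optional presentation time override.
#' @return An event tibble (see [spike_events()]), sorted by time.
#' @examples
#' img <- matrix(0, 5, 5); img[3, 3] <- 1
#' encode_image(img, encoder_params(isi_jitter = FALSE, rate_jitter_sd = 0))
#' @export
encode_image <- function(img, params = encoder_params(), t0 = 0,
                         duration = NULL) {
  stopifnot(inherits(params, "encoder_params"))
  if (any(img < 0) || any(img > 1))
    abort("pixel intensities must lie in [0, 1]")
  if (is.null(duration)) duration <- params$duration
  active <- which(img > 0, arr.ind = TRUE)
  if (nrow(active) == 0)
    return(spike_events(time = double(), row = integer(), col = integer()))

  out_t <- vector("list", nrow(active))
  for (i in seq_len(nrow(active))) {
    v <- img[active[i, 1], active[i, 2]]
    mu <- v / params$base_period
    rate <- if (params$rate_jitter_sd > 0)
      max(0, rnorm(1, mu, params$rate_jitter_sd * mu)) else mu
    if (rate <= 0) { out_t[[i]] <- double(); next }
    isi <- 1 / rate
    gaps <- double(0)
    block <- max(16L, ceiling(duration / isi * if (params$isi_jitter) 3 else 1.5))
    while (sum(gaps) < duration) {
      g <- if (params$isi_jitter) isi * runif(block) else rep(isi, block)
      gaps <- c(gaps, g)
    }
    tt <- cumsum(c(0, gaps))
    out_t[[i]] <- t0 + tt[tt < duration]
  }
  n_per <- lengths(out_t)
  ev <- tibble(time = unlist(out_t),
               layer = 0L, map = 1L,
               row = rep(as.integer(active[, 1]), n_per),
               col = rep(as.integer(active[, 2]), n_per),
               kind = "input")
  ev[order(ev$time, method = "radix"), ]
}

#' Concatenate stimuli into one continuous event stream
#'
#' Stimuli are encoded back-to-back with no separator or marker events: the
#' network sees a single continuous stream. A separate presentation log
#' (start time, duration, label) is returned for readout and metrics only.
#' Per-stimulus durations can be scaled by fixed or random factors to
#' emulate variable presentation times.
#'
#' @param stimuli A tibble with a list-column `image` (matrices in `[0, 1]`)
#'   and a column `label`, as returned by [generate_toy_set()]; or a plain
#'   list of matrices (then supply `labels`).
#' @param params An [encoder_params()] object.
#' @param labels Class labels when `stimuli` is a list.
#' @param duration_factors Per-stimulus multiplicative factors on
#'   `params$duration` (recycled); e.g. `runif(n, 0.1, 1.9)` for randomized
#'   presentation times.
#' @return A `spike_stream`: list with `events` (one tibble, time-sorted)
#'   and `log` (tibble `stimulus`, `label`, `t_start`, `duration`).
#' @export
make_stream <- function(stimuli, params = encoder_params(), labels = NULL,
                        duration_factors = 1) {
  if (is.data.frame(stimuli)) {
    labels <- stimuli$label
    images <- stimuli$image
  } else {
    images <- stimuli
  }
  n <- length(images)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  durations <- params$duration * rep_len(duration_factors, n)
  if (any(durations <= 0)) abort("durations must be positive")
  starts <- cumsum(c(0, durations))[seq_len(n)]
  parts <- vector("list", n)
  for (i in seq_len(n))
    parts[[i]] <- encode_image(images[[i]], params, t0 = starts[i],
                               duration = durations[i])
  events <- bind_rows(parts)
  events <- events[order(events$time, method = "radix"), ]
  structure(
    list(events = events,
         log = tibble(stimulus = seq_len(n), label = labels,
                      t_start = starts, duration = durations)),
    class = "spike_stream")
}

#' @export
print.spike_stream <- function(x, ...) {
  cat(sprintf("<spike_stream> %d stimuli, %d events, total duration %g\n",
              nrow(x$log), nrow(x$events),
              max(x$log$t_start + x$log$duration)))
  invisible(x)
}

# ---- IDX (MNIST container) and PGM readers/writers -------------------------

#' Read and write IDX image/label files
#'
#' The IDX binary container used by the MNIST distribution. Pixel values
#' 0..255 are scaled to `[0, 1]` exactly by division by 255.
#'
#' @param path File path (uncompressed IDX).
#' @return `read_idx_images()`: a list of intensity matrices;
#'   `read_idx_labels()`: an integer vector.
#' @export
read_idx_images <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2051L)) abort("not an IDX image file (bad magic number)")
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  nr <- readBin(con, "integer", 1, size = 4, endian = "big")
  nc <- readBin(con, "integer", 1, size = 4, endian = "big")
  raw <- readBin(con, "integer", n * nr * nc, size = 1, signed = FALSE)
  if (length(raw) != n * nr * nc) abort("truncated IDX image file")
  lapply(seq_len(n), function(i) {
    # IDX stores row-major; fill the matrix by row
    matrix(raw[((i - 1) * nr * nc + 1):(i * nr * nc)] / 255,
           nrow = nr, ncol = nc, byrow = TRUE)
  })
}

#' @rdname read_idx_images
#' @export
read_idx_labels <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2049L)) abort("not an IDX label file (bad magic number)")
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  lab <- readBin(con, "integer", n, size = 1, signed = FALSE)
  if (length(lab) != n) abort("truncated IDX label file")
  as.integer(lab)
}

#' @rdname read_idx_images
#' @param images List of matrices in `[0, 1]` (quantized to 0..255 on
#'   write).
#' @export
write_idx_images <- function(images, path) {
  nr <- nrow(images[[1]]); nc <- ncol(images[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(2051L, length(images), nr, nc), con, size = 4, endian = "big")
  for (img in images)
    writeBin(as.integer(round(t(img) * 255)), con, size = 1)
  invisible(path)
}

#' @rdname read_idx_images
#' @param labels Integer labels in 0..255.
#' @export
write_idx_labels <- function(labels, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(2049L, length(labels)), con, size = 4, endian = "big")
  writeBin(as.integer(labels), con, size = 1)
  invisible(path)
}

#' Read or write a PGM grayscale image
#'
#' Supports ASCII (`P2`) and binary (`P5`) portable graymaps on read;
#' writes ASCII `P2`. Intensities are scaled to `[0, 1]` by the file's
#' maxval.
#'
#' @param path File path.
#' @return A matrix of intensities in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5")) abort("not a PGM file (expected P2 or P5)")
  tok <- character(0)
  buf <- ""
  while (length(tok) < 3) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (length(ch) == 0 || ch == "") abort("truncated PGM header")
    if (ch == "#") {  # comment: skip to end of line
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1))
        if (ch == "\n" || ch == "") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { tok <- c(tok, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  nc <- as.integer(tok[1]); nr <- as.integer(tok[2])
  maxval <- as.integer(tok[3])
  if (magic == "P5") {
    px <- readBin(con, "integer", nr * nc, size = 1, signed = FALSE)
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    px <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    px <- px[seq_len(min(length(px), nr * nc))]
  }
  if (length(px) != nr * nc) abort("truncated PGM pixel data")
  matrix(px / maxval, nrow = nr, ncol = nc, byrow = TRUE)
}

#' @rdname read_pgm
#' @param img Matrix of intensities in `[0, 1]`.
#' @export
write_pgm <- function(img, path) {
  vals <- as.integer(round(t(img) * 255))
  lines <- c("P2", paste(ncol(img), nrow(img)), "255",
             paste(vals, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
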