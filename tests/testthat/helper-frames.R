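# small random sensor frames used across tests
random_frame <- function(n = 60, d = 3, n_classes = 3, seed = 1,
                         sensor_names = paste0("S", seq_len(d))) {
  withr::with_seed(seed, {
    labels <- sample.int(n_classes, n, replace = TRUE)
    centers <- matrix(seq_len(n_classes * d), n_classes, d)
    feats <- centers[labels, , drop = FALSE] + matrix(rnorm(n * d, sd = 0.5), n, d)
    sensor_frame(feats, labels, sensor_names = sensor_names,
                 n_classes = n_classes)
  })
}

# 1-D frame from explicit (value, label) pairs on a named sensor
frame_1d <- function(values, labels, name = "S1", n_classes = max(labels)) {
  sensor_frame(matrix(values, ncol = 1), labels, sensor_names = name,
               n_classes = n_classes)
}

# gaussian class-separated frame: class c centred at gap * (c - 1) per sensor
gaussian_frame <- function(n_per_class = 40, d = 2, n_classes = 3, gap = 4,
                           sd = 1, seed = 1) {
  withr::with_seed(seed, {
    labels <- rep(seq_len(n_classes), each = n_per_class)
    feats <- matrix(gap * (labels - 1), length(labels), d) +
      matrix(rnorm(length(labels) * d, sd = sd), length(labels), d)
    sensor_frame(feats, labels, n_classes = n_classes)
  })
}
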