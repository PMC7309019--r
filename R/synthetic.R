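#' Configuration for the synthetic e-nose spoilage generator
#'
#' Describes a simulated monitoring run of a perishable sample under a
#' multichannel gas-sensor array: a minute-resolution time series whose
#' quality label advances irreversibly from 1 (excellent) to `n_classes`
#' (spoiled) at fixed time boundaries, with each *informative* sensor
#' responding to the quality class through a per-class additive gain (rising
#' monotonically with spoilage, as volatile concentrations do) on top of a
#' sensor-specific baseline, Gaussian read noise, and an optional linear
#' drift. *Noise* sensors have class-independent means (all-zero gain rows)
#' and carry no label information by construction.
#'
#' @param n_samples Number of samples (minutes). Default 2200, the per-cut
#'   series length of the public beef-quality recordings this generator
#'   emulates.
#' @param d_sensors Number of sensor channels. Default 11.
#' @param n_classes Number of quality classes. Default 4.
#' @param boundaries Strictly increasing fractions in (0, 1) at which the
#'   label advances; length `n_classes - 1`. Default `c(0.25, 0.5, 0.75)`
#'   (equal dwell time per class).
#' @param baseline Numeric vector (`d_sensors`) of baseline responses.
#' @param gains `d_sensors x n_classes` matrix of class-response gains;
#'   a row of zeros makes that sensor a pure-noise channel.
#' @param noise_sd Per-sensor Gaussian noise standard deviations.
#' @param drift Per-sensor linear drift slope (response units per minute).
#'   Default 0.
#' @param sensor_names Channel names; default [mq_sensor_names()] truncated/
#'   recycled to `d_sensors`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 2200L, d_sensors = 11L,
                             n_classes = 4L,
                             boundaries = c(0.25, 0.5, 0.75),
                             baseline = NULL, gains = NULL,
                             noise_sd = 0.35, drift = 0,
                             sensor_names = NULL) {
  n_samples <- as.integer(n_samples)
  d_sensors <- as.integer(d_sensors)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L || d_sensors < 1L || n_samples < 1L)
    spvs_stop("need n_samples >= 1, d_sensors >= 1, n_classes >= 2",
              "spvs_config_error")
  if (length(boundaries) != n_classes - 1L ||
      any(boundaries <= 0) || any(boundaries >= 1) ||
      any(diff(boundaries) <= 0))
    spvs_stop("boundaries must be n_classes - 1 strictly increasing fractions in (0, 1)",
              "spvs_config_error")
  if (is.null(baseline)) baseline <- seq(1, 3, length.out = d_sensors)
  if (is.null(gains)) {
    gains <- outer(seq(0.9, 1.3, length.out = d_sensors), 0:(n_classes - 1L))
  }
  gains <- as.matrix(gains)
  if (!all(dim(gains) == c(d_sensors, n_classes)))
    spvs_stop("gains must be d_sensors x n_classes", "spvs_config_error")
  noise_sd <- rep_len(noise_sd, d_sensors)
  if (any(noise_sd < 0))
    spvs_stop("noise_sd must be non-negative", "spvs_config_error")
  drift <- rep_len(drift, d_sensors)
  if (is.null(sensor_names)) {
    sensor_names <- rep_len(mq_sensor_names(), max(d_sensors, 1L))[seq_len(d_sensors)]
    if (d_sensors > length(mq_sensor_names()))
      sensor_names <- make.unique(sensor_names)
  }
  structure(list(n_samples = n_samples, d_sensors = d_sensors,
                 n_classes = n_classes, boundaries = boundaries,
                 baseline = baseline, gains = gains, noise_sd = noise_sd,
                 drift = drift, sensor_names = sensor_names),
            class = "synthetic_config")
}

#' Which sensors of a configuration carry label information
#'
#' @param config A [synthetic_config()].
#' @return Logical vector: `TRUE` for sensors whose gain row is not constant
#'   across classes (informative), `FALSE` for pure-noise channels.
#' @export
informative_sensors <- function(config) {
  apply(config$gains, 1L, function(g) max(g) - min(g) > 0)
}

#' Generate a synthetic e-nose dataset
#'
#' Draws a [sensor_frame()] from a [synthetic_config()]: the label is a
#' non-decreasing step function of time with class proportions fixed exactly
#' by the boundary schedule, and sensor `j` at minute `t` reads
#' `baseline[j] + gains[j, class(t)] + drift[j] * t + N(0, noise_sd[j]^2)`.
#' The mask is all-true; failures are injected separately with
#' [generate_masks()]. Generation is a pure function of `(config, seed)`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed.
#' @return A [sensor_frame()] with `time_index = 1:n_samples` (minutes).
#' @export
#' @examples
#' fr <- generate_enose(synthetic_config(n_samples = 400), seed = 1)
#' all(diff(fr$labels) >= 0)  # spoilage is irreversible
generate_enose <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  d <- config$d_sensors
  class_sizes <- boundary_sizes(config$boundaries, n)
  labels <- rep.int(seq_len(config$n_classes), class_sizes)
  t_min <- seq_len(n)
  mu <- matrix(config$baseline, n, d, byrow = TRUE) +
    t(config$gains[, labels, drop = FALSE]) +
    outer(t_min, config$drift)
  feats <- withr::with_seed(seed, {
    mu + matrix(stats::rnorm(n * d), n, d) %*% diag(config$noise_sd, d)
  })
  sensor_frame(feats, labels, sensor_names = config$sensor_names,
               time_index = t_min, n_classes = config$n_classes)
}

# internal: per-class sample counts from boundary fractions (cumulative
# rounding, so proportions match the schedule exactly and sum to n)
boundary_sizes <- function(boundaries, n) {
  cuts <- c(0L, as.integer(round(boundaries * n)), n)
  sizes <- diff(cuts)
  if (any(sizes <= 0))
    spvs_stop("boundaries too close together for n_samples", "spvs_config_error")
  sizes
}

#' Named benchmark presets for the synthetic generator
#'
#' Fixed, documented configurations used throughout the test suite:
#'
#' * `redundant_informative` — 9 of 11 sensors informative with
#'   well-separated class gains (adjacent classes about 3 noise SDs apart
#'   per sensor); the regime in which a voting ensemble should be nearly
#'   immune to losing most of its sensors.
#' * `half_noise` — 6 informative sensors and 5 pure-noise sensors whose
#'   per-class means are equal by construction.
#' * `hard_overlap` — all 11 sensors informative but with heavily
#'   overlapping class responses (adjacent classes under 1 noise SD apart).
#'
#' @param name One of the preset names above.
#' @return A [synthetic_config()].
#' @export
preset_benchmark <- function(name = c("redundant_informative", "half_noise",
                                      "hard_overlap")) {
  name <- match.arg(name)
  d <- 11L
  C <- 4L
  step <- function(per_sensor) outer(per_sensor, 0:(C - 1L))
  if (name == "redundant_informative") {
    gains <- step(c(seq(0.9, 1.3, length.out = 9L), 0, 0))
    synthetic_config(gains = gains, noise_sd = c(rep(0.35, 9L), rep(0.5, 2L)))
  } else if (name == "half_noise") {
    gains <- step(c(seq(0.9, 1.3, length.out = 6L), rep(0, 5L)))
    synthetic_config(gains = gains, noise_sd = c(rep(0.35, 6L), rep(0.5, 5L)))
  } else {
    gains <- step(seq(0.9, 1.3, length.out = d))
    synthetic_config(gains = gains, noise_sd = 1.6)
  }
}
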