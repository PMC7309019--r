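#' Fit per-sensor normalization statistics
#'
#' Gas-sensor channels differ widely in dynamic range, which distorts any
#' distance-based classifier; responses are therefore rescaled per sensor
#' before training. Statistics are computed only over available
#' (`mask = TRUE`) cells and only on training data — test data is transformed
#' with the training-set statistics via [apply_normalization()].
#'
#' @param frame A non-empty [sensor_frame()].
#' @param method `"minmax"` (default; maps the training range to `[0, 1]`)
#'   or `"zscore"` (centre by mean, scale by sample standard deviation,
#'   denominator `n - 1`).
#' @return An object of class `normalization_stats` with per-sensor `center`
#'   (min or mean) and `scale` (range or sd).
#' @export
#' @examples
#' fr <- sensor_frame(cbind(a = c(2, 4, 6)), c(1, 2, 3), sensor_names = "a")
#' fit_normalization(fr)$center  # per-sensor minimum
fit_normalization <- function(frame, method = c("minmax", "zscore")) {
  stopifnot(inherits(frame, "sensor_frame"))
  method <- match.arg(method)
  if (nrow(frame$features) == 0L)
    spvs_stop("cannot fit normalization on an empty frame", "spvs_empty_input")
  d <- ncol(frame$features)
  center <- scale_ <- numeric(d)
  for (j in seq_len(d)) {
    v <- frame$features[frame$mask[, j], j]
    if (length(v) == 0L)
      spvs_stop(sprintf("sensor '%s' has no available cells",
                        frame$sensor_names[j]), "spvs_empty_input")
    if (method == "minmax") {
      center[j] <- min(v)
      scale_[j] <- max(v) - min(v)
    } else {
      center[j] <- mean(v)
      scale_[j] <- if (length(v) > 1L) stats::sd(v) else 0
    }
  }
  structure(list(method = method, center = center, scale = scale_,
                 sensor_names = frame$sensor_names),
            class = "normalization_stats")
}

#' Apply normalization statistics to a sensor frame
#'
#' Transforms every available cell as `(x - center) / scale`; a sensor whose
#' training column was constant (`scale = 0`) maps to 0. No clipping is
#' performed: test values outside the training range transform to values
#' outside `[0, 1]`. Masked cells are set to `NA` in the output so they can
#' never be consumed downstream.
#'
#' @param frame A [sensor_frame()].
#' @param stats A `normalization_stats` object fitted on training data whose
#'   sensor names match `frame`.
#' @return A transformed [sensor_frame()].
#' @export
apply_normalization <- function(frame, stats) {
  stopifnot(inherits(frame, "sensor_frame"),
            inherits(stats, "normalization_stats"))
  if (!identical(stats$sensor_names, frame$sensor_names))
    spvs_stop("normalization stats and frame disagree on sensor names",
              "spvs_config_error")
  feats <- frame$features
  feats[!frame$mask] <- NA_real_
  sc <- ifelse(stats$scale > 0, stats$scale, 1)
  feats <- sweep(sweep(feats, 2L, stats$center, "-"), 2L, sc, "/")
  feats[, stats$scale == 0] <- feats[, stats$scale == 0, drop = FALSE] * 0
  feats[!frame$mask] <- NA_real_
  sensor_frame(feats, frame$labels, frame$mask, frame$sensor_names,
               frame$time_index, frame$n_classes)
}
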