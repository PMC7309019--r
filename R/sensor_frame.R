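#' Default MQ-series sensor names of an 11-channel e-nose
#'
#' The metal-oxide-semiconductor gas sensors of the 11-channel beef-quality
#' e-nose array (each selective for a different family of volatiles, e.g.
#' MQ136 for hydrogen sulfide, MQ137 for ammonia).
#'
#' @return Character vector of 11 sensor identifiers.
#' @export
mq_sensor_names <- function() {
  c("MQ135", "MQ136", "MQ137", "MQ138", "MQ2", "MQ3",
    "MQ4", "MQ5", "MQ6", "MQ8", "MQ9")
}

#' Construct a sensor frame
#'
#' The central data container: a table of time-stamped e-nose samples with an
#' `n x d` numeric feature matrix (one column per gas sensor), an integer
#' quality label per sample (1 = excellent ... 4 = spoiled by default), and a
#' logical availability mask of the same shape as the features. A cell whose
#' mask entry is `FALSE` represents a failed/unavailable sensor reading and is
#' never consumed by any classifier in this package.
#'
#' @param features Numeric matrix, `n` samples by `d` sensors.
#' @param labels Integer vector of length `n` with values in `1..n_classes`.
#' @param mask Logical matrix, same shape as `features`; `TRUE` = available.
#'   Default: all available.
#' @param sensor_names Character vector of `d` unique sensor identifiers.
#' @param time_index Optional numeric vector of length `n` (minutes).
#' @param n_classes Number of quality classes `C`; defaults to
#'   `max(4, max(labels))`.
#' @return An object of class `sensor_frame`.
#' @export
#' @examples
#' x <- matrix(rnorm(20), 10, 2)
#' sensor_frame(x, rep(1:2, 5), sensor_names = c("MQ2", "MQ3"))
sensor_frame <- function(features, labels, mask = NULL, sensor_names = NULL,
                         time_index = NULL, n_classes = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  d <- ncol(features)
  labels <- as.integer(labels)
  if (is.null(sensor_names)) {
    sensor_names <- colnames(features) %||% paste0("S", seq_len(d))
  }
  if (is.null(mask)) mask <- matrix(TRUE, n, d)
  mask <- as.matrix(mask)
  if (length(labels) != n)
    spvs_stop("labels must have one entry per row of features", "spvs_invalid_frame")
  if (!all(dim(mask) == c(n, d)))
    spvs_stop("mask must have the same dimensions as features", "spvs_invalid_frame")
  if (!is.logical(mask))
    spvs_stop("mask must be logical", "spvs_invalid_frame")
  if (anyDuplicated(sensor_names) || length(sensor_names) != d)
    spvs_stop("sensor_names must be d unique identifiers", "spvs_invalid_frame")
  if (n > 0L && (anyNA(labels) || min(labels) < 1L))
    spvs_stop("labels must be positive integers", "spvs_invalid_frame")
  if (is.null(n_classes)) n_classes <- max(4L, if (n > 0L) max(labels) else 0L)
  n_classes <- as.integer(n_classes)
  if (n > 0L && max(labels) > n_classes)
    spvs_stop("labels exceed n_classes", "spvs_invalid_frame")
  if (!is.null(time_index) && length(time_index) != n)
    spvs_stop("time_index must have one entry per sample", "spvs_invalid_frame")
  colnames(features) <- sensor_names
  colnames(mask) <- sensor_names
  structure(
    list(features = features, labels = labels, mask = mask,
         sensor_names = sensor_names, time_index = time_index,
         n_classes = n_classes),
    class = "sensor_frame"
  )
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat(sprintf("<sensor_frame> %d samples x %d sensors, %d classes\n",
              nrow(x$features), ncol(x$features), x$n_classes))
  cat("  sensors:", paste(x$sensor_names, collapse = ", "), "\n")
  if (nrow(x$features) > 0L) {
    cat("  label counts:",
        paste(sprintf("%d:%d", seq_len(x$n_classes),
                      tabulate(x$labels, x$n_classes)), collapse = " "), "\n")
  }
  n_missing <- sum(!x$mask)
  if (n_missing > 0L) cat("  unavailable cells:", n_missing, "\n")
  invisible(x)
}

#' @export
dim.sensor_frame <- function(x) dim(x$features)

#' Subset the rows of a sensor frame
#'
#' @param frame A [sensor_frame()].
#' @param i Row index vector (integer or logical).
#' @return A `sensor_frame` with the selected rows.
#' @export
frame_rows <- function(frame, i) {
  sensor_frame(frame$features[i, , drop = FALSE], frame$labels[i],
               frame$mask[i, , drop = FALSE], frame$sensor_names,
               frame$time_index[i], frame$n_classes)
}

#' Column-mapping configuration for delimited sensor tables
#'
#' Binds the columns of a CSV file to the sensor-frame schema, so files with
#' arbitrary headers (e.g. the public beef-quality measurements) can be read
#' without code changes.
#'
#' @param sensors Character vector of sensor column names; default the 11
#'   MQ-series names of [mq_sensor_names()].
#' @param label Name of the integer label column.
#' @param time Optional name of a minute/time column.
#' @return A list of class `sensor_mapping`.
#' @export
sensor_mapping <- function(sensors = mq_sensor_names(), label = "label",
                           time = NULL) {
  stopifnot(is.character(sensors), length(sensors) >= 1L,
            is.character(label), length(label) == 1L)
  structure(list(sensors = sensors, label = label, time = time),
            class = "sensor_mapping")
}

#' Read an e-nose dataset from CSV
#'
#' Reads a delimited text file (comma-separated, header row, '.' decimal)
#' into a [sensor_frame()]. Sensor cells that are blank or unparseable are
#' kept in the frame but flagged unavailable (`mask = FALSE`) with a warning
#' naming the affected rows; row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param mapping A [sensor_mapping()] naming the label column and sensor
#'   columns present in the header.
#' @param n_classes Number of quality classes; default `max(4, max(labels))`.
#' @return A [sensor_frame()].
#' @export
read_sensor_csv <- function(path, mapping = sensor_mapping(), n_classes = NULL) {
  if (!file.exists(path))
    spvs_stop(sprintf("file not found: %s", path), "spvs_io_error")
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = c("", "NA"))
  if (!mapping$label %in% names(raw))
    spvs_stop(sprintf("label column '%s' not found in header", mapping$label),
              "spvs_config_error")
  missing_sensors <- setdiff(mapping$sensors, names(raw))
  if (length(missing_sensors) == length(mapping$sensors))
    spvs_stop("none of the configured sensor columns are present",
              "spvs_config_error")
  if (length(missing_sensors) > 0L)
    spvs_stop(sprintf("sensor columns missing from header: %s",
                      paste(missing_sensors, collapse = ", ")),
              "spvs_config_error")
  if (nrow(raw) == 0L)
    spvs_stop("no usable rows in input", "spvs_empty_input")
  labels <- suppressWarnings(as.integer(raw[[mapping$label]]))
  if (anyNA(labels))
    spvs_stop("label column contains non-integer values", "spvs_config_error")
  feats <- suppressWarnings(
    vapply(raw[mapping$sensors], as.numeric, numeric(nrow(raw)))
  )
  feats <- matrix(feats, nrow = nrow(raw),
                  dimnames = list(NULL, mapping$sensors))
  mask <- !is.na(feats)
  if (any(!mask)) {
    bad_rows <- sort(unique(which(!mask, arr.ind = TRUE)[, 1L]))
    warning(sprintf("masked %d unparseable/blank sensor cell(s) in row(s): %s",
                    sum(!mask),
                    paste(utils::head(bad_rows, 20L), collapse = ", ")))
  }
  time_index <- if (!is.null(mapping$time) && mapping$time %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[mapping$time]]))
  } else NULL
  sensor_frame(feats, labels, mask, mapping$sensors, time_index, n_classes)
}

#' Write a sensor frame to CSV
#'
#' Masked (unavailable) cells are written as empty fields so that a re-read
#' with [read_sensor_csv()] reproduces features (to printed precision),
#' labels, and mask.
#'
#' @param frame A [sensor_frame()].
#' @param path Output file path.
#' @param mapping A [sensor_mapping()] whose sensor names match the frame.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(frame, path,
                             mapping = sensor_mapping(frame$sensor_names)) {
  stopifnot(inherits(frame, "sensor_frame"))
  feats <- frame$features
  feats[!frame$mask] <- NA_real_
  out <- as.data.frame(apply(feats, 2L, function(col) {
    ifelse(is.na(col), "", format(col, digits = 17, trim = TRUE,
                                  scientific = FALSE))
  }, simplify = FALSE), check.names = FALSE, optional = TRUE)
  if (nrow(frame$features) == 0L) {
    out <- as.data.frame(matrix(character(), 0L, length(frame$sensor_names),
                                dimnames = list(NULL, frame$sensor_names)))
  }
  out[[mapping$label]] <- frame$labels
  if (!is.null(frame$time_index) && !is.null(mapping$time))
    out[[mapping$time]] <- frame$time_index
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) spvs_stop(sprintf("cannot write to %s", path), "spvs_io_error")
  invisible(path)
}
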