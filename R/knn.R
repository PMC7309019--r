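#' Fit a k-nearest-neighbour classifier
#'
#' kNN has no optimisation step: fitting stores the (restricted) training
#' matrix and labels verbatim. Works on any subset of sensors, including a
#' single sensor — the per-sensor ensemble use case.
#'
#' @param train A [sensor_frame()]; the selected sensor cells must all be
#'   available (callers restrict rows first).
#' @param sensors Integer or character index of the sensors to use;
#'   `NULL` (default) = all sensors.
#' @param k Number of neighbours, `1 <= k <= n`. Default 1.
#' @param cfg A [distance_config()].
#' @return An object of class `knn_model`.
#' @export
knn_fit <- function(train, sensors = NULL, k = 1L, cfg = distance_config()) {
  xy <- extract_training(train, sensors)
  k <- as.integer(k)
  if (k < 1L || k > nrow(xy$x))
    spvs_stop(sprintf("k = %d must be in [1, n = %d]", k, nrow(xy$x)),
              "spvs_config_error")
  structure(list(x = xy$x, y = xy$y, k = k, cfg = cfg,
                 n_classes = train$n_classes, sensor_names = xy$names),
            class = "knn_model")
}

#' Predict with a k-nearest-neighbour classifier
#'
#' Finds the `k` nearest stored training points (distance ties broken by
#' lowest training-row index) and returns the plurality label among their
#' labels; label ties break to the smallest label value. `type = "prob"`
#' returns the neighbour-vote fractions per class.
#'
#' @param object A `knn_model`.
#' @param newdata Numeric matrix (rows = queries) or a single feature vector,
#'   with as many columns as the model has sensors.
#' @param type `"class"` (integer labels) or `"prob"` (vote-fraction matrix).
#' @param ... Unused.
#' @export
predict.knn_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_query_matrix(newdata, length(object$sensor_names))
  D <- dist_matrix(X, object$x, object$cfg)
  C <- object$n_classes
  votes <- matrix(0, nrow(X), C)
  idx <- seq_len(nrow(object$x))
  for (i in seq_len(nrow(X))) {
    nb <- idx[order(D[i, ], idx)][seq_len(object$k)]
    votes[i, ] <- tabulate(object$y[nb], C)
  }
  if (type == "prob") return(votes / object$k)
  as.integer(apply(votes, 1L, which.max))
}

# internal: restrict a frame to a sensor subset, enforcing full availability
extract_training <- function(train, sensors) {
  stopifnot(inherits(train, "sensor_frame"))
  if (nrow(train$features) == 0L)
    spvs_stop("training frame is empty", "spvs_empty_input")
  if (is.null(sensors)) sensors <- seq_along(train$sensor_names)
  if (is.character(sensors)) sensors <- match(sensors, train$sensor_names)
  if (anyNA(sensors) || any(sensors < 1L) || any(sensors > ncol(train$features)))
    spvs_stop("unknown sensor in subset", "spvs_config_error")
  if (!all(train$mask[, sensors]))
    spvs_stop("training data must have no masked cells in the selected sensors",
              "spvs_masked_training")
  list(x = train$features[, sensors, drop = FALSE], y = train$labels,
       names = train$sensor_names[sensors])
}

as_query_matrix <- function(newdata, d) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != d)
    spvs_stop(sprintf("query has %d features; model expects %d",
                      ncol(newdata), d), "spvs_config_error")
  storage.mode(newdata) <- "double"
  newdata
}
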