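#' Fit a single-plurality-voting-system (SPVS) ensemble
#'
#' Trains one univariate base classifier per sensor channel (a homogeneous
#' ensemble: the same family for all sensors). At prediction time each
#' available sensor's classifier casts one vote on its own channel value and
#' the plurality winner is the ensemble label; failed sensors are skipped
#' entirely, which is what makes the ensemble tolerant to sensor loss.
#'
#' @param train A [sensor_frame()] with no masked cells (training data is
#'   assumed loss-free; failures are a test-time phenomenon).
#' @param family Base-classifier family: `"knn"`, `"tree"`, or `"lda"`.
#' @param ... Hyperparameters forwarded to [knn_fit()], [tree_fit()], or
#'   [lda_fit()] (e.g. `k`, `cfg`, `max_depth`, `ridge`).
#' @param tie Vote tie-break: `"smallest"` (default; the freshest quality
#'   label) or `"largest"` (most spoiled — the safety-conservative choice
#'   for deployment).
#' @param fallback Policy when every sensor of a sample has failed:
#'   `"error"` (default) or `"majority"` (predict the training-set majority
#'   label and flag the row).
#' @return An object of class `spvs_model`.
#' @export
#' @examples
#' fr <- generate_enose(preset_benchmark("redundant_informative"), seed = 1)
#' m <- spvs_fit(frame_rows(fr, 1:200), family = "tree")
spvs_fit <- function(train, family = c("knn", "tree", "lda"), ...,
                     tie = c("smallest", "largest"),
                     fallback = c("error", "majority")) {
  stopifnot(inherits(train, "sensor_frame"))
  family <- match.arg(family)
  tie <- match.arg(tie)
  fallback <- match.arg(fallback)
  if (nrow(train$features) == 0L)
    spvs_stop("training frame is empty", "spvs_empty_input")
  if (!all(train$mask))
    spvs_stop("SPVS training requires loss-free data (no masked cells)",
              "spvs_masked_training")
  fit_fun <- switch(family, knn = knn_fit, tree = tree_fit, lda = lda_fit)
  models <- lapply(seq_along(train$sensor_names),
                   function(j) fit_fun(train, sensors = j, ...))
  counts <- tabulate(train$labels, train$n_classes)
  structure(list(models = models, family = family,
                 sensor_names = train$sensor_names,
                 n_classes = train$n_classes, tie = tie, fallback = fallback,
                 majority_label = which.max(counts)),
            class = "spvs_model")
}

#' Plurality vote over a set of labels
#'
#' Returns the modal label; ties break to the smallest label by default, or
#' to the largest (most-spoiled) when `tie = "largest"`.
#'
#' @param votes Non-empty integer vector of labels.
#' @param n_classes Number of classes; default `max(votes)`.
#' @param tie `"smallest"` or `"largest"`.
#' @return The winning label (integer scalar).
#' @export
#' @examples
#' plurality_vote(c(3, 3, 1))   # 3
#' plurality_vote(c(1, 2, 1, 2))  # 1 (tie rule)
plurality_vote <- function(votes, n_classes = NULL,
                           tie = c("smallest", "largest")) {
  tie <- match.arg(tie)
  if (length(votes) == 0L)
    spvs_stop("cannot take a plurality over zero votes", "spvs_empty_input")
  votes <- as.integer(votes)
  if (is.null(n_classes)) n_classes <- max(votes)
  counts <- tabulate(votes, n_classes)
  if (tie == "smallest") which.max(counts)
  else n_classes + 1L - which.max(rev(counts))
}

#' Predict with an SPVS ensemble under a sensor-availability mask
#'
#' Each sensor `j` with `available[j] = TRUE` contributes one vote — its
#' classifier's label on feature `x[j]`; unavailable sensors are skipped and
#' their classifiers never invoked. The returned label is the plurality
#' winner over the cast votes.
#'
#' @param model An [spvs_fit()] ensemble.
#' @param x Numeric feature vector of length `d`, or an `n x d` matrix.
#' @param available Logical vector/matrix shaped like `x`; `NULL` = all
#'   available.
#' @param vote_type `"hard"` (default: one label vote per sensor) or
#'   `"prob"` (experimental: sums the base classifiers' class-probability
#'   vectors instead of hard labels).
#' @return For a vector `x`: a list with `label`, `votes` (per-class counts),
#'   `n_votes` and `fallback`. For a matrix: a data.frame with columns
#'   `label`, `n_votes`, `fallback` plus one vote-count column per class.
#' @export
spvs_predict <- function(model, x, available = NULL,
                         vote_type = c("hard", "prob")) {
  stopifnot(inherits(model, "spvs_model"))
  vote_type <- match.arg(vote_type)
  single <- is.null(dim(x))
  X <- as_query_matrix(x, length(model$sensor_names))
  if (is.null(available)) available <- matrix(TRUE, nrow(X), ncol(X))
  if (is.null(dim(available))) available <- matrix(available, nrow = 1L)
  if (!all(dim(available) == dim(X)))
    spvs_stop("availability mask must be shaped like x", "spvs_config_error")
  C <- model$n_classes
  n <- nrow(X)
  tally <- matrix(0, n, C)
  for (j in seq_len(ncol(X))) {
    rows <- which(available[, j])
    if (length(rows) == 0L) next
    if (vote_type == "hard") {
      lab <- predict(model$models[[j]], X[rows, j, drop = FALSE])
      tally[cbind(rows, lab)] <- tally[cbind(rows, lab)] + 1
    } else {
      pr <- predict(model$models[[j]], X[rows, j, drop = FALSE], type = "prob")
      tally[rows, ] <- tally[rows, ] + pr
    }
  }
  n_votes <- rowSums(available)
  labels <- integer(n)
  is_fallback <- n_votes == 0L
  if (any(is_fallback) && model$fallback == "error")
    spvs_stop("all sensors unavailable for at least one sample (fallback = 'error')",
              "spvs_all_failed")
  for (i in which(!is_fallback)) {
    labels[i] <- if (model$tie == "smallest") which.max(tally[i, ])
                 else C + 1L - which.max(rev(tally[i, ]))
  }
  labels[is_fallback] <- model$majority_label
  if (single) {
    return(list(label = labels[1L], votes = tally[1L, ],
                n_votes = n_votes[1L], fallback = is_fallback[1L]))
  }
  out <- data.frame(label = labels, n_votes = n_votes, fallback = is_fallback)
  colnames(tally) <- paste0("votes_", seq_len(C))
  cbind(out, as.data.frame(tally))
}

#' @export
predict.spvs_model <- function(object, newdata, mask = NULL, ...) {
  res <- spvs_predict(object, newdata, mask, ...)
  if (is.data.frame(res)) res$label else res$label
}

#' Save / load an SPVS model archive
#'
#' Serialises a trained ensemble to a single versioned JSON file (manifest +
#' full numeric payload at maximum precision) so a model round-trips exactly:
#' the reloaded model reproduces predictions bit-identically.
#'
#' @param model An [spvs_fit()] ensemble.
#' @param path File path for the archive.
#' @return `spvs_save`: `path`, invisibly. `spvs_load`: the restored
#'   `spvs_model`.
#' @export
spvs_save <- function(model, path) {
  stopifnot(inherits(model, "spvs_model"))
  payload <- list(
    format = "spvs-model", version = 1L,
    family = model$family, sensor_names = model$sensor_names,
    n_classes = model$n_classes, tie = model$tie, fallback = model$fallback,
    majority_label = model$majority_label,
    normalization = if (!is.null(model$normalization))
      unclass(model$normalization),
    models = lapply(model$models, serialize_base_model)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname spvs_save
#' @param path File path of a saved archive.
#' @export
spvs_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(p$format, "spvs-model"))
    spvs_stop("not an SPVS model archive", "spvs_io_error")
  models <- lapply(p$models, deserialize_base_model)
  norm <- if (length(p$normalization) > 0L)
    structure(p$normalization, class = "normalization_stats")
  structure(list(models = models, family = p$family,
                 sensor_names = p$sensor_names,
                 n_classes = as.integer(p$n_classes), tie = p$tie,
                 fallback = p$fallback,
                 majority_label = as.integer(p$majority_label),
                 normalization = norm),
            class = "spvs_model")
}

serialize_base_model <- function(m) {
  if (inherits(m, "knn_model")) {
    list(kind = "knn", x = as.numeric(m$x), n = nrow(m$x), y = m$y, k = m$k,
         metric = m$cfg$metric, q = m$cfg$q, n_classes = m$n_classes,
         sensor_names = m$sensor_names)
  } else if (inherits(m, "tree_model")) {
    list(kind = "tree", root = m$root, n_classes = m$n_classes,
         sensor_names = m$sensor_names,
         nodes = lapply(m$nodes, function(nd) {
           if (nd$leaf) list(leaf = TRUE, label = nd$label, prop = nd$prop,
                             n = nd$n)
           else list(leaf = FALSE, var = nd$var, threshold = nd$threshold,
                     left = nd$left, right = nd$right, n = nd$n)
         }))
  } else if (inherits(m, "lda_model")) {
    list(kind = "lda", classes = m$classes, means = as.numeric(m$means),
         priors = m$priors, pooled_cov = as.numeric(m$pooled_cov),
         W = as.numeric(m$W), w_cols = ncol(m$W), ridge = m$ridge,
         n_classes = m$n_classes, sensor_names = m$sensor_names)
  } else spvs_stop("unknown base model", "spvs_io_error")
}

deserialize_base_model <- function(p) {
  d <- length(p$sensor_names)
  if (p$kind == "knn") {
    structure(list(x = matrix(p$x, nrow = p$n), y = as.integer(p$y),
                   k = as.integer(p$k),
                   cfg = distance_config(p$metric, p$q),
                   n_classes = as.integer(p$n_classes),
                   sensor_names = p$sensor_names),
              class = "knn_model")
  } else if (p$kind == "tree") {
    nodes <- lapply(p$nodes, function(nd) {
      if (isTRUE(nd$leaf)) list(leaf = TRUE, label = as.integer(nd$label),
                                prop = as.numeric(nd$prop), n = as.integer(nd$n))
      else list(leaf = FALSE, var = as.integer(nd$var),
                threshold = as.numeric(nd$threshold),
                left = as.integer(nd$left), right = as.integer(nd$right),
                n = as.integer(nd$n))
    })
    structure(list(nodes = nodes, root = as.integer(p$root),
                   n_classes = as.integer(p$n_classes),
                   sensor_names = p$sensor_names),
              class = "tree_model")
  } else if (p$kind == "lda") {
    k <- length(p$classes)
    structure(list(classes = as.integer(p$classes),
                   means = matrix(as.numeric(p$means), nrow = k),
                   priors = as.numeric(p$priors),
                   pooled_cov = matrix(as.numeric(p$pooled_cov), nrow = d),
                   W = matrix(as.numeric(p$W), ncol = p$w_cols),
                   ridge = as.numeric(p$ridge),
                   n_classes = as.integer(p$n_classes),
                   sensor_names = p$sensor_names),
              class = "lda_model")
  } else spvs_stop("unknown base model kind in archive", "spvs_io_error")
}
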