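#' Stratified k-fold split
#'
#' Partitions the rows of a frame into `k` folds for cross-validation. By
#' default the split is stratified by label: within each class the shuffled
#' indices are dealt round-robin, with a single global dealing pointer shared
#' across classes so that per-class fold counts *and* overall fold sizes both
#' differ by at most one. If any class has fewer samples than `k`, a warning
#' is issued and the split falls back to unstratified dealing.
#'
#' @param frame A [sensor_frame()] (or an integer label vector).
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed for the shuffle.
#' @param stratify Stratify by label? Default `TRUE`.
#' @return A list of `k` elements, each `list(train = <idx>, test = <idx>)`;
#'   the `test` sets partition `1:n`.
#' @export
kfold_split <- function(frame, k = 5L, seed = 1L, stratify = TRUE) {
  labels <- if (inherits(frame, "sensor_frame")) frame$labels
            else as.integer(frame)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L || k > n)
    spvs_stop(sprintf("k = %d must be in [2, n = %d]", k, n),
              "spvs_config_error")
  if (stratify && min(table(labels)) < k) {
    warning("a class has fewer samples than k; falling back to unstratified folds")
    stratify <- FALSE
  }
  fold_of <- integer(n)
  withr::with_seed(seed, {
    if (stratify) {
      p <- 0L
      for (c in sort(unique(labels))) {
        idx <- sample(which(labels == c))
        fold_of[idx] <- (p + seq_along(idx) - 1L) %% k + 1L
        p <- (p + length(idx)) %% k
      }
    } else {
      fold_of[sample.int(n)] <- (seq_len(n) - 1L) %% k + 1L
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Confusion matrix of true vs predicted labels
#'
#' @param truth,pred Integer label vectors of equal length.
#' @param n_classes Number of classes `C`; default `max(truth, pred)`.
#' @return A `C x C` integer matrix, rows = true label, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, n_classes = NULL) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  if (is.null(n_classes)) n_classes <- max(truth, pred)
  cm <- matrix(tabulate((truth - 1L) * n_classes + pred,
                        n_classes * n_classes),
               n_classes, n_classes, byrow = TRUE)
  dimnames(cm) <- list(true = seq_len(n_classes), pred = seq_len(n_classes))
  cm
}

#' Classification accuracy, sensitivity and specificity from a confusion matrix
#'
#' CA is the trace over the total. Sensitivity and specificity are one-vs-rest
#' per class — `TP / (TP + FN)` and `TN / (TN + FP)` — combined by macro
#' averaging (default: the unweighted mean over classes present in the
#' truth; absent classes are skipped) or micro averaging (pooled counts).
#'
#' @param cm A confusion matrix (rows = truth), e.g. from
#'   [confusion_matrix()].
#' @param averaging `"macro"` (default) or `"micro"`.
#' @return Named numeric vector `c(ca, sensitivity, specificity)`, all in
#'   `[0, 1]`.
#' @export
compute_metrics <- function(cm, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) spvs_stop("empty confusion matrix", "spvs_empty_input")
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  present <- rowSums(cm) > 0
  if (averaging == "macro") {
    sens <- mean((tp / (tp + fn))[present])
    spec <- mean((tn / (tn + fp))[present])
  } else {
    sens <- sum(tp[present]) / sum((tp + fn)[present])
    spec <- sum(tn[present]) / sum((tn + fp)[present])
  }
  c(ca = sum(tp) / total, sensitivity = sens, specificity = spec)
}

#' Evaluate a single joint classifier under a failure mask
#'
#' The baseline against which the voting ensemble is compared: one
#' classifier trained on all sensors jointly. A joint classifier cannot skip
#' a failed sensor, so masked test cells must be filled before prediction —
#' by the training-set per-sensor mean (default), by zero, or the affected
#' rows skipped entirely (`"skip"`; the confusion matrix then covers fewer
#' samples). With an all-true mask the imputation path is never touched.
#'
#' @param train,test [sensor_frame()]s with identical sensors.
#' @param masks Logical availability matrix shaped like `test$features`, or
#'   `NULL` for no failures.
#' @param family `"knn"`, `"tree"`, or `"lda"`.
#' @param ... Hyperparameters for the base-classifier fit.
#' @param imputation `"mean"`, `"zero"`, or `"skip"`.
#' @return A confusion matrix over the evaluated test samples.
#' @export
evaluate_single <- function(train, test, masks = NULL,
                            family = c("knn", "tree", "lda"), ...,
                            imputation = c("mean", "zero", "skip")) {
  family <- match.arg(family)
  imputation <- match.arg(imputation)
  fit_fun <- switch(family, knn = knn_fit, tree = tree_fit, lda = lda_fit)
  model <- fit_fun(train, sensors = NULL, ...)
  X <- test$features
  if (is.null(masks)) masks <- matrix(TRUE, nrow(X), ncol(X))
  keep <- rep(TRUE, nrow(X))
  if (any(!masks)) {
    if (imputation == "skip") {
      keep <- rowSums(!masks) == 0L
    } else {
      fill <- if (imputation == "mean") colMeans(train$features)
              else numeric(ncol(X))
      for (j in seq_len(ncol(X))) X[!masks[, j], j] <- fill[j]
    }
  }
  if (!any(keep))
    spvs_stop("no test rows left after listwise skipping", "spvs_empty_input")
  pred <- predict(model, X[keep, , drop = FALSE])
  confusion_matrix(test$labels[keep], pred, test$n_classes)
}

#' Evaluate an SPVS ensemble under a failure mask
#'
#' Trains the per-sensor voting ensemble on the training frame and predicts
#' each test row under its availability mask; failed sensors are excluded
#' from the vote, never imputed.
#'
#' @inheritParams evaluate_single
#' @param ... Hyperparameters forwarded to [spvs_fit()].
#' @return A confusion matrix over the test samples.
#' @export
evaluate_spvs <- function(train, test, masks = NULL,
                          family = c("knn", "tree", "lda"), ...) {
  family <- match.arg(family)
  model <- spvs_fit(train, family, ...)
  res <- spvs_predict(model, test$features, masks)
  confusion_matrix(test$labels, res$label, test$n_classes)
}

#' Run the full cross-validated method comparison
#'
#' The benchmark experiment: for each base-classifier family, both methods
#' (single joint classifier vs SPVS voting ensemble) are evaluated under
#' both conditions (clean test data vs the failure mixture of `profile`)
#' with stratified k-fold cross-validation. Folds are shuffled from the
#' master seed; each fold's failure masks come from a fold-specific sub-seed
#' (see [derive_seed()]), so the whole experiment is reproducible from
#' `(frame, config, seed)`.
#'
#' @param frame A [sensor_frame()].
#' @param families Character subset of `c("knn", "lda", "tree")`.
#' @param k Number of CV folds. Default 5.
#' @param profile A [failure_profile()] for the missing condition.
#' @param seed Master seed.
#' @param conditions Subset of `c("clean", "missing")`.
#' @param methods Subset of `c("single", "spvs")`.
#' @param imputation Imputation policy for the single baseline under
#'   missing data (see [evaluate_single()]).
#' @param averaging Metric averaging, `"macro"` or `"micro"`.
#' @param hyperparams Named list of per-family hyperparameter lists, e.g.
#'   `list(knn = list(k = 1), tree = list(max_depth = 20))`.
#' @return An `evaluation_report`: a data.frame with one row per
#'   (family, method, condition, fold) plus per-row `ca`, `sensitivity`,
#'   `specificity`; run metadata in attributes. `summary()` or `print()`
#'   show the fold-averaged table.
#' @export
run_experiment <- function(frame, families = c("knn", "lda", "tree"),
                           k = 5L, profile = ten_tier_profile(), seed = 1L,
                           conditions = c("clean", "missing"),
                           methods = c("single", "spvs"),
                           imputation = "mean", averaging = "macro",
                           hyperparams = list()) {
  stopifnot(inherits(frame, "sensor_frame"))
  families <- match.arg(families, several.ok = TRUE)
  conditions <- match.arg(conditions, c("clean", "missing"), several.ok = TRUE)
  methods <- match.arg(methods, c("single", "spvs"), several.ok = TRUE)
  folds <- kfold_split(frame, k, seed = derive_seed(seed, "folds"))
  rows <- list()
  for (f in seq_along(folds)) {
    train <- frame_rows(frame, folds[[f]]$train)
    test <- frame_rows(frame, folds[[f]]$test)
    stats <- fit_normalization(train)
    train_n <- apply_normalization(train, stats)
    test_n <- apply_normalization(test, stats)
    # normalization is fit on the training fold only; masks apply to test
    fold_masks <- generate_masks(nrow(test$features), ncol(test$features),
                                 profile,
                                 derive_seed(seed, paste0("masks-fold-", f)))
    for (family in families) {
      hp <- hyperparams[[family]] %||% list()
      for (method in methods) {
        for (condition in conditions) {
          masks <- if (condition == "missing") fold_masks$mask else NULL
          cm <- if (method == "single") {
            do.call(evaluate_single,
                    c(list(train_n, test_n, masks, family,
                           imputation = imputation), hp))
          } else {
            do.call(evaluate_spvs, c(list(train_n, test_n, masks, family), hp))
          }
          m <- compute_metrics(cm, averaging)
          rows[[length(rows) + 1L]] <- data.frame(
            family = family, method = method, condition = condition,
            fold = f, ca = m[["ca"]], sensitivity = m[["sensitivity"]],
            specificity = m[["specificity"]])
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  structure(report,
            class = c("evaluation_report", "data.frame"),
            seed = seed, k = k, profile = profile,
            imputation = imputation, averaging = averaging,
            hyperparams = hyperparams)
}

#' Fold-averaged summary of an evaluation report
#'
#' @param object An `evaluation_report` from [run_experiment()].
#' @param ... Unused.
#' @return A data.frame with one row per (family, method, condition) and the
#'   mean CA, sensitivity and specificity over folds.
#' @export
summary.evaluation_report <- function(object, ...) {
  agg <- stats::aggregate(object[c("ca", "sensitivity", "specificity")],
                          object[c("family", "method", "condition")], mean)
  ord <- order(match(agg$family, c("knn", "lda", "tree")),
               match(agg$method, c("single", "spvs")),
               match(agg$condition, c("clean", "missing")))
  agg[ord, , drop = FALSE]
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("SPVS benchmark: %d folds, seed %d, imputation '%s', %s averaging\n",
              attr(x, "k"), attr(x, "seed"), attr(x, "imputation"),
              attr(x, "averaging")))
  cat(sprintf("%-6s %-18s  %6s %6s %6s\n", "Base", "Method", "CA", "Sens", "Spec"))
  for (i in seq_len(nrow(s))) {
    label <- paste0(if (s$condition[i] == "missing") "Missing:" else "",
                    if (s$method[i] == "single") "Single CL" else "SPVS")
    cat(sprintf("%-6s %-18s  %6.4f %6.4f %6.4f\n", s$family[i], label,
                s$ca[i], s$sensitivity[i], s$specificity[i]))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report_folds.csv` (one row per grid cell per fold),
#' `report_mean.csv` (fold averages), and `report.txt` (the printed summary
#' table), plus `run_config.txt` recording seed and policies.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report), file.path(dir, "report_folds.csv"),
                   row.names = FALSE)
  utils::write.csv(summary(report), file.path(dir, "report_mean.csv"),
                   row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  prof <- attr(report, "profile")
  cfg <- c(sprintf("seed: %d", attr(report, "seed")),
           sprintf("folds: %d", attr(report, "k")),
           sprintf("imputation: %s", attr(report, "imputation")),
           sprintf("averaging: %s", attr(report, "averaging")),
           sprintf("profile_fractions: %s",
                   paste(prof$fractions, collapse = ",")),
           sprintf("profile_counts: %s", paste(prof$counts, collapse = ",")))
  writeLines(cfg, file.path(dir, "run_config.txt"))
  invisible(dir)
}
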