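#' Fit a linear discriminant analysis classifier
#'
#' Computes per-class mean vectors, the pooled within-class covariance
#' (denominator `n - C`), class priors (training frequencies), and the
#' discriminant projection matrix `W` — the leading eigenvectors (at most
#' `C - 1`) of the within/between scatter problem, retained for the
#' dimension-reduction pathway. Classification uses the Gaussian
#' shared-covariance discriminant with Bayes' rule (see
#' [predict.lda_model()]). On a single sensor the model degenerates to 1-D
#' Gaussian Bayes with pooled variance.
#'
#' @param train A [sensor_frame()] with at least two classes present.
#' @param sensors Sensor subset (integer or character); `NULL` = all.
#' @param ridge Non-negative ridge added to the diagonal of the pooled
#'   covariance; guards zero-variance channels. Default `1e-9`.
#' @return An object of class `lda_model`.
#' @export
lda_fit <- function(train, sensors = NULL, ridge = 1e-9) {
  xy <- extract_training(train, sensors)
  X <- xy$x
  y <- xy$y
  C <- train$n_classes
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    spvs_stop("LDA needs at least two classes in the training data",
              "spvs_degenerate_fit")
  d <- ncol(X)
  n <- nrow(X)
  means <- do.call(rbind, lapply(classes, function(c)
    colMeans(X[y == c, , drop = FALSE])))
  priors <- as.numeric(tabulate(y, C)[classes]) / n
  Sw <- matrix(0, d, d)
  for (ci in seq_along(classes)) {
    Xi <- X[y == classes[ci], , drop = FALSE]
    Xc <- sweep(Xi, 2L, means[ci, ], "-")
    Sw <- Sw + crossprod(Xc)
  }
  pooled <- Sw / max(n - length(classes), 1L)
  pooled <- pooled + diag(ridge, d)
  if (rcond_ok(pooled) < .Machine$double.eps)
    spvs_stop(paste("pooled within-class covariance is singular;",
                    "refit with a positive ridge"), "spvs_singular_fit")
  gmean <- colMeans(X)
  Sb <- matrix(0, d, d)
  for (ci in seq_along(classes)) {
    dv <- means[ci, ] - gmean
    Sb <- Sb + sum(y == classes[ci]) * tcrossprod(dv)
  }
  eig <- eigen(solve(pooled, Sb))   # eigenvectors of the scatter problem
  n_keep <- min(length(classes) - 1L, d)
  W <- Re(eig$vectors[, seq_len(n_keep), drop = FALSE])
  structure(list(classes = classes, means = means, priors = priors,
                 pooled_cov = pooled, W = W, ridge = ridge,
                 n_classes = C, sensor_names = xy$names),
            class = "lda_model")
}

rcond_ok <- function(m) {
  tryCatch(rcond(m), error = function(e) 0)
}

#' Predict with a linear discriminant classifier
#'
#' Evaluates the shared-covariance Gaussian discriminant
#' `x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c` for every class and
#' applies Bayes' rule; posteriors are the softmax of the discriminants and
#' sum to 1. Ties break to the smallest label. Classes absent from training
#' receive posterior 0.
#'
#' @param object An `lda_model`.
#' @param newdata Numeric matrix or single feature vector.
#' @param type `"class"` or `"prob"` (posterior matrix, `n x n_classes`).
#' @param ... Unused.
#' @export
predict.lda_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_query_matrix(newdata, length(object$sensor_names))
  Sinv <- solve(object$pooled_cov)
  A <- object$means %*% Sinv                       # k x d
  disc <- X %*% t(A)                               # n x k
  const <- -0.5 * rowSums(A * object$means) + log(object$priors)
  disc <- sweep(disc, 2L, const, "+")
  post_present <- exp(disc - apply(disc, 1L, max))
  post_present <- post_present / rowSums(post_present)
  post <- matrix(0, nrow(X), object$n_classes)
  post[, object$classes] <- post_present
  if (type == "prob") return(post)
  as.integer(apply(post, 1L, which.max))
}
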