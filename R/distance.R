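#' Distance configuration for k-nearest-neighbour classification
#'
#' @param metric One of `"euclidean"` (default, the metric used throughout
#'   the benchmark experiments), `"manhattan"`, `"minkowski"`, `"cosine"`.
#' @param q Minkowski order, a finite positive real; used only when
#'   `metric = "minkowski"`.
#' @return A list of class `distance_config`.
#' @export
distance_config <- function(metric = c("euclidean", "manhattan", "minkowski",
                                       "cosine"), q = 2) {
  metric <- match.arg(metric)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0)
    spvs_stop("Minkowski order q must be a finite positive number",
              "spvs_config_error")
  structure(list(metric = metric, q = q), class = "distance_config")
}

#' Distance between two feature vectors
#'
#' Implements the four distances available to the kNN base classifier:
#' Euclidean `sqrt(sum((x - y)^2))`, Manhattan `sum(|x - y|)`, Minkowski
#' `(sum(|x - y|^q))^(1/q)`, and cosine distance
#' `1 - (x . y) / (||x|| ||y||)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param cfg A [distance_config()].
#' @return A non-negative scalar.
#' @export
#' @examples
#' sensor_distance(c(0, 0), c(3, 4))  # 5
sensor_distance <- function(x, y, cfg = distance_config()) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  switch(cfg$metric,
    euclidean = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    minkowski = sum(abs(x - y)^cfg$q)^(1 / cfg$q),
    cosine = {
      nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
      if (nx == 0 || ny == 0)
        spvs_stop("cosine distance is undefined for a zero vector",
                  "spvs_undefined_distance")
      1 - sum(x * y) / (nx * ny)
    }
  )
}

rowwise_dist <- function(A, B, f) {
  out <- matrix(0, nrow(A), nrow(B))
  tB <- t(B)
  for (i in seq_len(nrow(A))) out[i, ] <- f(A[i, ], tB)
  out
}

# internal: m x n matrix of distances between rows of A (queries) and rows of
# B (training points); vectorised per metric
dist_matrix <- function(A, B, cfg) {
  A <- rbind(A); B <- rbind(B)
  switch(cfg$metric,
    euclidean = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      sqrt(pmax(d2, 0))
    },
    manhattan = rowwise_dist(A, B, function(x, tB) colSums(abs(tB - x))),
    minkowski = rowwise_dist(A, B, function(x, tB)
      colSums(abs(tB - x)^cfg$q)^(1 / cfg$q)),
    cosine = {
      na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
      if (any(na == 0) || any(nb == 0))
        spvs_stop("cosine distance is undefined for a zero vector",
                  "spvs_undefined_distance")
      1 - tcrossprod(A / na, B / nb)
    }
  )
}
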