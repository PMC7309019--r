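#' Fit a CART-style classification tree
#'
#' Greedy binary splitting on (sensor, threshold) pairs maximising Gini
#' impurity decrease. Candidate thresholds are midpoints between consecutive
#' distinct sorted values of a sensor. Recursion stops at node purity, at the
#' stopping limits, or when no split yields a positive impurity decrease.
#' Ties between equally good splits break to the lowest sensor index, then
#' the smallest threshold, so the fit is deterministic and independent of
#' input row order.
#'
#' Defaults grow an unrestricted tree (training accuracy 1 on any consistent
#' dataset); set `max_depth` / `min_leaf` / `min_decrease` to regularise.
#'
#' @param train A [sensor_frame()] with no masked cells in the selected
#'   sensors.
#' @param sensors Sensor subset (integer or character); `NULL` = all.
#' @param max_depth Maximum tree depth (root = depth 0). Default 30.
#' @param min_split Minimum node size to attempt a split. Default 2.
#' @param min_leaf Minimum samples in each child. Default 1.
#' @param min_decrease Minimum Gini impurity decrease to accept a split.
#'   Default 0 (any positive decrease).
#' @return An object of class `tree_model`: a flat node table with integer
#'   child links; leaves carry the predicted label and class proportions.
#' @export
tree_fit <- function(train, sensors = NULL, max_depth = 30L, min_split = 2L,
                     min_leaf = 1L, min_decrease = 0) {
  xy <- extract_training(train, sensors)
  C <- train$n_classes
  nodes <- new.env(parent = emptyenv())
  nodes$list <- list()
  add_node <- function(node) {
    nodes$list[[length(nodes$list) + 1L]] <- node
    length(nodes$list)
  }
  gini <- function(counts) {
    n <- sum(counts)
    1 - sum((counts / n)^2)
  }
  grow <- function(idx, depth) {
    y <- xy$y[idx]
    counts <- tabulate(y, C)
    n <- length(idx)
    make_leaf <- function() {
      add_node(list(leaf = TRUE, label = which.max(counts),
                    prop = counts / n, n = n))
    }
    if (depth >= max_depth || n < min_split || gini(counts) == 0)
      return(make_leaf())
    best <- find_best_split(xy$x[idx, , drop = FALSE], y, C, min_leaf)
    if (is.null(best) || best$decrease <= 0 || best$decrease < min_decrease)
      return(make_leaf())
    go_left <- xy$x[idx, best$var] <= best$threshold
    node_id <- add_node(list(leaf = FALSE))  # reserve slot for preorder ids
    left <- grow(idx[go_left], depth + 1L)
    right <- grow(idx[!go_left], depth + 1L)
    nodes$list[[node_id]] <- list(leaf = FALSE, var = best$var,
                                  threshold = best$threshold,
                                  left = left, right = right, n = n)
    node_id
  }
  root <- grow(seq_along(xy$y), 0L)
  structure(list(nodes = nodes$list, root = root, n_classes = C,
                 sensor_names = xy$names),
            class = "tree_model")
}

# internal: best (var, threshold) by Gini decrease over all candidate
# midpoints; vectorised with cumulative class counts per sorted feature
find_best_split <- function(X, y, C, min_leaf) {
  n <- length(y)
  parent_gini <- 1 - sum((tabulate(y, C) / n)^2)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    xs <- X[o, j]
    ys <- y[o]
    # cumulative class counts after each sorted position
    cum <- apply(vapply(seq_len(C), function(c) ys == c, logical(n)), 2L, cumsum)
    cum <- rbind(cum)
    pos <- which(xs[-n] < xs[-1L])                # split after position pos
    pos <- pos[pos >= min_leaf & (n - pos) >= min_leaf]
    if (length(pos) == 0L) next
    nl <- pos
    nr <- n - pos
    gl <- 1 - rowSums((cum[pos, , drop = FALSE] / nl)^2)
    cnt_r <- matrix(cum[n, ], length(pos), C, byrow = TRUE) -
      cum[pos, , drop = FALSE]
    gr <- 1 - rowSums((cnt_r / nr)^2)
    dec <- parent_gini - (nl * gl + nr * gr) / n
    b <- which.max(dec)                            # first max = smallest threshold
    if (is.null(best) || dec[b] > best$decrease + 1e-12) {
      best <- list(var = j, threshold = (xs[pos[b]] + xs[pos[b] + 1L]) / 2,
                   decrease = dec[b])
    }
  }
  best
}

#' Predict with a classification tree
#'
#' Routes each query by threshold comparisons (`value <= threshold` goes
#' left) and returns the leaf's majority label (`type = "class"`, ties to the
#' smallest label) or its class-proportion vector (`type = "prob"`).
#'
#' @param object A `tree_model`.
#' @param newdata Numeric matrix or single feature vector.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @export
predict.tree_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_query_matrix(newdata, length(object$sensor_names))
  labels <- integer(nrow(X))
  probs <- matrix(0, nrow(X), object$n_classes)
  for (i in seq_len(nrow(X))) {
    id <- object$root
    repeat {
      node <- object$nodes[[id]]
      if (node$leaf) break
      id <- if (X[i, node$var] <= node$threshold) node$left else node$right
    }
    labels[i] <- node$label
    probs[i, ] <- node$prop
  }
  if (type == "prob") probs else labels
}
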