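# Minimal CART regression tree used by the cohort imputer.
#
# Greedy binary splitting on the feature/threshold pair with the largest
# squared-error reduction, grown until nodes are pure or too small to split
# (the defaults of the common scikit-learn regressor). Entirely
# deterministic: ties are broken by the first feature and the lowest
# threshold. This is intentionally small -- no pruning, no categorical
# features -- because the imputer only ever predicts bounded editing levels
# from a handful of numeric covariates.

#' Fit a regression tree
#'
#' @param x numeric matrix of features (rows = observations)
#' @param y numeric response
#' @param min_split smallest node that may be split (default 2)
#' @param max_depth maximum depth (default 30)
#' @return an object of class `rtree`
#' @export
rtree_fit <- function(x, y, min_split = 2L, max_depth = 30L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), !anyNA(x), !anyNA(y))
  grow <- function(idx, depth) {
    yy <- y[idx]
    node <- list(value = mean(yy))
    if (length(idx) < min_split || depth >= max_depth ||
        stats::var(yy) == 0 || is.na(stats::var(yy)))
      return(node)
    best <- NULL
    base_sse <- sum((yy - mean(yy))^2)
    m <- length(idx)
    for (j in seq_len(ncol(x))) {
      v <- x[idx, j]
      o <- order(v)
      vs <- v[o]; ys <- yy[o]
      # candidate split after each position where the value changes;
      # prefix sums give both child SSEs for all candidates at once
      cut <- which(vs[-m] < vs[-1])
      if (!length(cut)) next
      cy <- cumsum(ys); cy2 <- cumsum(ys^2)
      nl <- cut; nr <- m - cut
      sl <- cy[cut]; sr <- cy[m] - sl
      sse <- (cy2[cut] - sl^2 / nl) + (cy2[m] - cy2[cut] - sr^2 / nr)
      k <- which.min(sse)
      if (is.null(best) || sse[k] < best$sse - 1e-12)
        best <- list(j = j, t = (vs[cut[k]] + vs[cut[k] + 1L]) / 2,
                     sse = sse[k])
    }
    if (is.null(best) || best$sse >= base_sse - 1e-12) return(node)
    l <- x[idx, best$j] <= best$t
    node$feature <- best$j
    node$threshold <- best$t
    node$left <- grow(idx[l], depth + 1L)
    node$right <- grow(idx[!l], depth + 1L)
    node
  }
  structure(list(root = grow(seq_along(y), 0L), p = ncol(x)), class = "rtree")
}

#' Predict from a regression tree
#'
#' @param object an `rtree`
#' @param newdata numeric matrix with the training feature columns
#' @param ... unused
#' @return numeric predictions
#' @export
predict.rtree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$p)
  one <- function(node, row) {
    while (!is.null(node$feature)) {
      node <- if (row[node$feature] <= node$threshold) node$left else node$right
    }
    node$value
  }
  apply(newdata, 1L, function(r) one(object$root, r))
}
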