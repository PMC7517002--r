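# Shannon entropy (base 2) of a label vector.
class_entropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain ratio of a binary split
#'
#' `GR = (Entropy(S) - sum_v |S_v|/|S| * Entropy(S_v)) / SplitInfo` with
#' base-2 logs, where the two subsets are the rows with `left` TRUE/FALSE
#' and `SplitInfo = -sum_v |S_v|/|S| * log2(|S_v|/|S|)`. Degenerate splits
#' (one side empty) return 0.
#'
#' @param y class labels.
#' @param left logical vector: TRUE for rows sent to the left child.
#' @return list with `gain`, `split_info`, `gain_ratio`.
#' @export
information_gain_ratio <- function(y, left) {
  n <- length(y)
  nl <- sum(left)
  if (nl == 0 || nl == n)
    return(list(gain = 0, split_info = 0, gain_ratio = 0))
  pl <- nl / n
  gain <- class_entropy(y) -
    pl * class_entropy(y[left]) - (1 - pl) * class_entropy(y[!left])
  si <- -pl * log2(pl) - (1 - pl) * log2(1 - pl)
  list(gain = gain, split_info = si, gain_ratio = gain / si)
}

# Best threshold for one continuous feature: candidate cuts at midpoints of
# consecutive sorted unique values, scored by gain ratio.
best_feature_split <- function(xj, y) {
  u <- sort(unique(xj))
  if (length(u) < 2) return(NULL)
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (t in cuts) {
    s <- information_gain_ratio(y, xj <= t)
    if (s$gain <= 0) next
    if (is.null(best) || s$gain_ratio > best$gain_ratio)
      best <- c(s, threshold = t)
  }
  best
}

majority_class <- function(y) {
  tab <- table(y)
  names(tab)[which.max(tab)]  # ties -> first level, deterministic
}

grow_tree <- function(x, y, epsilon, depth, max_depth, min_split) {
  if (length(unique(y)) == 1L)
    return(list(leaf = TRUE, class = as.character(y[1L]), n = length(y)))
  if (length(y) < min_split || depth >= max_depth)
    return(list(leaf = TRUE, class = majority_class(y), n = length(y)))
  splits <- lapply(seq_len(ncol(x)), function(j) best_feature_split(x[, j], y))
  ok <- !vapply(splits, is.null, logical(1))
  if (!any(ok))
    return(list(leaf = TRUE, class = majority_class(y), n = length(y)))
  gr <- vapply(splits, function(s) if (is.null(s)) -Inf else s$gain_ratio,
               numeric(1))
  j <- which.max(gr)
  if (gr[j] < epsilon)
    return(list(leaf = TRUE, class = majority_class(y), n = length(y)))
  t <- splits[[j]]$threshold
  left <- x[, j] <= t
  list(leaf = FALSE, feature = j, threshold = t, gain_ratio = gr[j],
       n = length(y),
       left = grow_tree(x[left, , drop = FALSE], y[left],
                        epsilon, depth + 1L, max_depth, min_split),
       right = grow_tree(x[!left, , drop = FALSE], y[!left],
                         epsilon, depth + 1L, max_depth, min_split))
}

#' Train a gain-ratio decision tree
#'
#' Recursive top-down induction: a node becomes a leaf when it is pure, too
#' small, at maximal depth, or when the best split's information gain ratio
#' falls below `epsilon`; otherwise the feature/threshold pair with the
#' largest gain ratio is chosen. Features are continuous, so splits are
#' binary thresholds at midpoints of consecutive sorted unique values (the
#' standard C4.5 adaptation of the categorical gain-ratio recursion).
#' No pruning is applied.
#'
#' @param x numeric feature matrix.
#' @param y class labels.
#' @param epsilon stop threshold on the gain ratio (default `1e-7`).
#' @param max_depth recursion cap.
#' @param min_split minimum node size to attempt a split.
#' @return object of class `"gr_tree"`; the root node's `gain_ratio` is the
#'   gain ratio of the chosen root split.
#' @export
train_dt <- function(x, y, epsilon = 1e-7, max_depth = 30L, min_split = 2L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) == 0) stop("empty training set")
  root <- grow_tree(x, y, epsilon, 0L, max_depth, min_split)
  structure(list(root = root, classes = levels(y), n_features = ncol(x),
                 feature_names = colnames(x), epsilon = epsilon),
            class = "gr_tree")
}

#' @export
predict.gr_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  walk <- function(node, row) {
    while (!node$leaf)
      node <- if (row[node$feature] <= node$threshold) node$left else node$right
    node$class
  }
  vapply(seq_len(nrow(X)), function(i) walk(object$root, X[i, ]), character(1))
}

#' @export
print.gr_tree <- function(x, ...) {
  count <- function(node) if (node$leaf) 1L else count(node$left) + count(node$right)
  cat(sprintf("<gr_tree> %d classes, %d leaves, epsilon = %g\n",
              length(x$classes), count(x$root), x$epsilon))
  invisible(x)
}
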