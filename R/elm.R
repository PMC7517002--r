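#' Train an extreme learning machine
#'
#' Single-hidden-layer network with random, fixed hidden parameters: input
#' weights and biases are drawn from a seeded uniform(-1, 1), the hidden
#' activations `H` are computed with the chosen activation, and the output
#' weights solve the least-squares system `H beta = Y` (one-hot targets)
#' through the Moore-Penrose pseudo-inverse, `beta = pinv(H) Y`. Prediction
#' is the arg-max of the output vector.
#'
#' `activation = "sigmoid"` is the classic random-feature form
#' `g(w'x + b)`; `"rbf"` uses radial units `exp(-|b| * ||x - w||^2)` with
#' random centres, for the kernel-flavoured variant.
#'
#' @param x numeric feature matrix.
#' @param y class labels.
#' @param M hidden-layer size (>= 1); default `min(10 * ncol(x), nrow(x))`.
#' @param seed integer seed for the random hidden parameters.
#' @param activation `"sigmoid"` (default) or `"rbf"`.
#' @return object of class `"elm"`.
#' @export
train_elm <- function(x, y, M = NULL, seed = 1,
                      activation = c("sigmoid", "rbf")) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (is.null(M)) M <- min(10L * ncol(x), nrow(x))
  if (M < 1) stop("hidden-layer size M must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  W <- matrix(runif(M * ncol(x), -1, 1), nrow = M)  # M x d input weights
  b <- runif(M, -1, 1)
  H <- elm_hidden(x, W, b, activation)
  Y <- stats::model.matrix(~ cls - 1, data.frame(cls = y))  # one-hot
  colnames(Y) <- levels(y)
  beta <- MASS::ginv(H) %*% Y
  structure(list(W = W, b = b, beta = beta, M = M, activation = activation,
                 classes = levels(y), n_features = ncol(x), seed = seed),
            class = "elm")
}

elm_hidden <- function(X, W, b, activation) {
  if (activation == "sigmoid") {
    A <- X %*% t(W) + matrix(b, nrow(X), length(b), byrow = TRUE)
    1 / (1 + exp(-A))
  } else {
    d2 <- outer(rowSums(X^2), rowSums(W^2), `+`) - 2 * tcrossprod(X, W)
    exp(-pmax(d2, 0) * matrix(abs(b), nrow(X), length(b), byrow = TRUE))
  }
}

#' @export
predict.elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features)
    stop("feature dimension mismatch")
  S <- elm_hidden(X, object$W, object$b, object$activation) %*% object$beta
  colnames(S) <- object$classes
  if (type == "score") return(S)
  object$classes[max.col(S, ties.method = "first")]
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("<elm> %d classes, M = %d hidden units (%s), seed = %d\n",
              length(x$classes), x$M, x$activation, x$seed))
  invisible(x)
}
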