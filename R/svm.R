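#' Hyperparameter grid for the RBF-SVM grid search
#'
#' Defaults are the customary coarse log2 grid: `C` in `2^(-5), 2^(-3), ...,
#' 2^15` and `gamma` in `2^(-15), 2^(-13), ..., 2^3`.
#'
#' @param C candidate penalty factors.
#' @param gamma candidate RBF widths.
#' @export
svm_grid <- function(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2)) {
  stopifnot(all(C > 0), all(gamma > 0))
  list(C = C, gamma = gamma)
}

# RBF kernel matrix exp(-gamma ||x - y||^2) between row sets.
rbf_kernel <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

# Binary soft-margin SVM: solve the dual QP
#   min 1/2 a' Q a - e' a,  y' a = 0,  0 <= a <= C,  Q = (y y') * K
# with quadprog (small ridge for strict positive-definiteness), then recover
# the intercept from on-margin support vectors.
svm_binary_fit <- function(X, y, C, gamma) {
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  Q <- (y %o% y) * K + diag(1e-8, n)
  sol <- quadprog::solve.QP(
    Dmat = Q, dvec = rep(1, n),
    Amat = cbind(y, diag(n), -diag(n)),
    bvec = c(0, rep(0, n), rep(-C, n)), meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  sv <- which(a > 1e-8)
  coef <- a[sv] * y[sv]
  f0 <- as.vector(K[, sv, drop = FALSE] %*% coef)
  on_margin <- sv[a[sv] > 1e-6 * C & a[sv] < C * (1 - 1e-6)]
  b <- if (length(on_margin) > 0) mean(y[on_margin] - f0[on_margin])
       else mean(y[sv] - f0[sv])
  list(sv_x = X[sv, , drop = FALSE], coef = coef, b = b, gamma = gamma)
}

svm_binary_decision <- function(fit, X) {
  as.vector(rbf_kernel(X, fit$sv_x, fit$gamma) %*% fit$coef) + fit$b
}

# One binary machine per unordered class pair (i < j); f > 0 favours i.
fit_ovo <- function(x, y, C, gamma) {
  lev <- levels(y)
  pairs <- utils::combn(lev, 2)
  fits <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    idx <- y %in% c(i, j)
    yy <- ifelse(y[idx] == i, 1, -1)
    svm_binary_fit(x[idx, , drop = FALSE], yy, C, gamma)
  })
  list(classes = lev, pair_i = pairs[1, ], pair_j = pairs[2, ], fits = fits)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a one-vs-one RBF-SVM with grid search
#'
#' Trains `k(k-1)/2` binary RBF soft-margin machines, one per class pair,
#' selecting `(C, gamma)` by stratified cross-validated accuracy over the
#' grid. Ties are broken towards the smallest `C`, then the smallest
#' `gamma`. With a single-cell grid the cross-validation is skipped.
#' Deterministic given `seed`.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y class labels (factor or character, >= 2 classes).
#' @param grid an [svm_grid()]; pass a single-cell grid to fix `(C, gamma)`.
#' @param cv_folds folds for the grid search (each class needs at least this
#'   many samples).
#' @param seed integer seed for the fold assignment.
#' @return object of class `"ovo_svm"` with elements `classes`, `pairs`,
#'   `C`, `gamma`, `cv_record` (per-cell accuracies).
#' @export
train_svm <- function(x, y, grid = svm_grid(), cv_folds = 5, seed = 1) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes to train an SVM")
  combos <- expand.grid(C = sort(grid$C), gamma = sort(grid$gamma))
  cv_record <- NULL
  if (nrow(combos) > 1) {
    if (any(table(y) < cv_folds))
      stop("every class needs at least `cv_folds` samples for the grid search")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    fold <- stratified_folds(y, cv_folds)
    acc <- vapply(seq_len(nrow(combos)), function(ci) {
      mean(vapply(seq_len(cv_folds), function(f) {
        tr <- fold != f
        m <- fit_ovo(x[tr, , drop = FALSE], droplevels(y[tr]),
                     combos$C[ci], combos$gamma[ci])
        mean(ovo_predict_class(m, x[!tr, , drop = FALSE]) == y[!tr])
      }, numeric(1)))
    }, numeric(1))
    cv_record <- cbind(combos, accuracy = acc)
    best <- which(acc == max(acc))
    # ties -> smallest C, then smallest gamma
    best <- best[order(combos$C[best], combos$gamma[best])][1L]
    combos <- combos[best, , drop = FALSE]
  }
  model <- fit_ovo(x, y, combos$C[1L], combos$gamma[1L])
  structure(list(classes = model$classes, pairs = model,
                 C = combos$C[1L], gamma = combos$gamma[1L],
                 n_features = ncol(x), cv_record = cv_record),
            class = "ovo_svm")
}

# Save/restore the global RNG state so seeded model fits don't perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Decision values for all pairs at once: rows = samples, cols = pairs.
svm_decision_matrix <- function(model, X) {
  m <- model$pairs
  matrix(vapply(m$fits, function(fit) svm_binary_decision(fit, X),
                numeric(nrow(X))),
         nrow = nrow(X))
}

ovo_predict_class <- function(m, X) {
  F <- matrix(vapply(m$fits, function(fit) svm_binary_decision(fit, X),
                     numeric(nrow(X))),
              nrow = nrow(X))
  apply(F, 1, function(f) pairwise_decision(m$classes, m$pair_i, m$pair_j,
                                            f)$ranking[1L])
}

#' Pairwise OvO decision record for one sample
#'
#' Bundles the signed decision values of every pairwise machine (`f > 0`
#' favours class `i` of the pair, boundary `f = 0` counted for `i`), derives
#' the vote tally (each pair contributes exactly one vote, so votes sum to
#' `k(k-1)/2`), and ranks the classes by votes with ties broken by the sum
#' of signed decision values in each class's favour.
#'
#' @param classes class names.
#' @param pair_i,pair_j class names of each pair.
#' @param f signed decision values, one per pair.
#' @return object of class `"pairwise_decision"` with `classes`, `pair_i`,
#'   `pair_j`, `f`, `votes` (named), `margin_sum` (named), `ranking`.
#' @export
pairwise_decision <- function(classes, pair_i, pair_j, f) {
  stopifnot(length(pair_i) == length(f), length(pair_j) == length(f))
  votes <- stats::setNames(integer(length(classes)), classes)
  msum <- stats::setNames(numeric(length(classes)), classes)
  for (p in seq_along(f)) {
    w <- if (f[p] >= 0) pair_i[p] else pair_j[p]
    votes[w] <- votes[w] + 1L
    msum[pair_i[p]] <- msum[pair_i[p]] + f[p]
    msum[pair_j[p]] <- msum[pair_j[p]] - f[p]
  }
  ranking <- classes[order(-votes, -msum)]
  structure(list(classes = classes, pair_i = pair_i, pair_j = pair_j,
                 f = f, votes = votes, margin_sum = msum, ranking = ranking),
            class = "pairwise_decision")
}

#' Pairwise decision values and votes for one sample
#'
#' @param model a trained [train_svm()] model.
#' @param x a single feature vector (or one-row matrix).
#' @return a [pairwise_decision()].
#' @export
svm_decide <- function(model, x) {
  x <- matrix(as.numeric(x), nrow = 1)
  if (ncol(x) != model$n_features)
    stop(sprintf("feature dimension mismatch: got %d, model expects %d",
                 ncol(x), model$n_features))
  f <- svm_decision_matrix(model, x)[1L, ]
  pairwise_decision(model$classes, model$pairs$pair_i, model$pairs$pair_j, f)
}

#' @export
predict.ovo_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features)
    stop(sprintf("feature dimension mismatch: got %d, model expects %d",
                 ncol(X), object$n_features))
  F <- svm_decision_matrix(object, X)
  if (type == "decision") return(F)
  vapply(seq_len(nrow(X)), function(i)
    pairwise_decision(object$classes, object$pairs$pair_i,
                      object$pairs$pair_j, F[i, ])$ranking[1L],
    character(1))
}

#' @export
print.ovo_svm <- function(x, ...) {
  cat(sprintf("<ovo_svm> %d classes, %d pairwise machines, C = %g, gamma = %g\n",
              length(x$classes), length(x$pairs$fits), x$C, x$gamma))
  invisible(x)
}
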