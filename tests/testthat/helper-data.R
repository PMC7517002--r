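# Shared fixtures built in code.

# Four well-separated 2-d Gaussian blobs.
blobs4 <- function(n_per = 25, sep = 3, seed = 1, noise = 1) {
  set.seed(seed)
  centers <- matrix(c(0, 0, sep, sep, sep, -sep, -sep, sep),
                    ncol = 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(n_per, centers[k, 1], noise),
          rnorm(n_per, centers[k, 2], noise))))
  list(x = X, y = factor(rep(c("a", "b", "c", "d"), each = n_per)))
}

# A pairwise decision over 4 classes with the given (or random) f values.
pd4 <- function(f = NULL, classes = c("A", "B", "C", "D")) {
  pairs <- combn(classes, 2)
  if (is.null(f)) f <- runif(ncol(pairs), -3, 3)
  pairwise_decision(classes, pairs[1, ], pairs[2, ], f)
}

# Demo-preset fused feature table, cached per session (used by several
# files; extraction costs a couple of seconds).
demo_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(synth_spec_demo(seed = 11))
      segs <- unlist(lapply(ds$recordings, segment_recording, window_s = 6),
                     recursive = FALSE)
      cache <<- extract_features(segs)
    }
    cache
  }
})

# Small hyperparameter grid so test-time grid searches stay cheap.
test_grid <- function() svm_grid(C = 2^c(0, 4, 8), gamma = 2^c(-4, -2, 0))
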