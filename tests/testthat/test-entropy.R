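test_that("constant and degenerate series follow the conventions", {
  const <- rep(2, 100)
  expect_equal(approximate_entropy(const), 0)
  expect_equal(sample_entropy(const), 0)
  expect_equal(fuzzy_entropy(const), 0)
  expect_error(wavelet_packet_entropy(rep(0, 64)), "total energy")
  expect_error(approximate_entropy(c(1, 2, 3)), "too short")
  apart <- (1:20)^2  # no pair of templates within a tiny tolerance
  expect_error(sample_entropy(apart, entropy_params(r_frac = 1e-6)),
               "undefined")
  expect_true(is.na(sample_entropy(apart, entropy_params(r_frac = 1e-6),
                                   if_undefined = "na")))
})

test_that("template entropies match the naive double-loop oracles", {
  set.seed(101)
  for (i in 1:12) {
    N <- sample(120:180, 1)
    m <- sample(2:3, 1)
    x <- rnorm(N) + (i %% 2) * sin(seq_len(N) / 3)  # mix white + oscillatory
    p <- entropy_params(m = m, r_frac = 0.2)
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, p), naive_apen(x, m, r),
                 tolerance = 1e-10)
    expect_equal(sample_entropy(x, p), naive_saen(x, m, r),
                 tolerance = 1e-10)
    expect_equal(fuzzy_entropy(x, p), naive_fuen(x, m, r),
                 tolerance = 1e-10)
  }
  # the deterministic 12-point example against the same oracles
  x <- rep(c(1, 2, 3), 4)
  r <- 0.2 * sd(x)
  expect_equal(approximate_entropy(x), naive_apen(x, 2, r), tolerance = 1e-10)
})

test_that("fuzzy membership is exactly one half at distance r", {
  fm <- entrofuse:::fuzzy_membership
  expect_equal(fm(1, 1), 0.5)
  expect_equal(fm(0, 1), 1)
  expect_lt(fm(2, 1), 0.5)
})

test_that("chaotic series score higher than periodic ones", {
  p <- entropy_params()
  for (seed in 1:3) {
    set.seed(seed)
    n <- 500
    x <- numeric(n); v <- runif(1, 0.2, 0.8)
    for (i in 1:n) { v <- 4 * v * (1 - v); x[i] <- v }  # logistic, a = 4
    s <- sin(2 * pi * 3 * seq_len(n) / n)
    expect_gt(approximate_entropy(x, p), approximate_entropy(s, p))
    expect_gt(sample_entropy(x, p), sample_entropy(s, p))
    expect_gt(fuzzy_entropy(x, p), fuzzy_entropy(s, p))
  }
})

test_that("features are amplitude-scale invariant and non-negative", {
  set.seed(202)
  p <- entropy_params()
  for (i in 1:10) {
    x <- rnorm(120) + 0.5 * sin(seq_len(120) / 5)
    c_ <- runif(1, 0.1, 50)
    expect_equal(approximate_entropy(c_ * x, p), approximate_entropy(x, p),
                 tolerance = 1e-9)
    expect_equal(sample_entropy(c_ * x, p), sample_entropy(x, p),
                 tolerance = 1e-9)
    expect_equal(fuzzy_entropy(c_ * x, p), fuzzy_entropy(x, p),
                 tolerance = 1e-9)
    expect_equal(wavelet_packet_entropy(c_ * x, p),
                 wavelet_packet_entropy(x, p), tolerance = 1e-9)
    expect_gte(approximate_entropy(x, p), 0)
    expect_gte(sample_entropy(x, p), 0)
  }
})

test_that("wavelet packet entropy is the Shannon entropy of band energies", {
  # degenerate and uniform energy distributions
  expect_equal(wpen_from_energies(c(5, 0, 0, 0, 0, 0, 0, 0)), 0)
  expect_equal(wpen_from_energies(rep(1, 8)), log(8))
  expect_error(wpen_from_energies(rep(0, 8)), "zero")

  set.seed(303)
  x <- rnorm(512)
  p <- entropy_params(wavelet = "db4", depth = 3)
  nodes <- wp_decompose(x, "db4", 3)
  expect_length(nodes, 8)
  E <- vapply(nodes, function(v) sum(v^2), numeric(1))
  # recomputation from the exported coefficients matches the one-call value
  expect_equal(wavelet_packet_entropy(x, p), wpen_from_energies(E),
               tolerance = 1e-12)
  # orthonormal filter bank: energy preserved, proportions sum to one
  expect_equal(sum(E), sum(x^2), tolerance = 1e-8)
  expect_equal(sum(E / sum(E)), 1)
  expect_lte(wavelet_packet_entropy(x, p), 3 * log(2))
  expect_gte(wavelet_packet_entropy(x, p), 0)
  # haar path too
  expect_lte(wavelet_packet_entropy(x, entropy_params(wavelet = "haar",
                                                      depth = 2)), log(4))
})

test_that("channel extraction composes the four features deterministically", {
  set.seed(404)
  x <- rnorm(256)
  cf <- extract_channel_features(x, "emg")
  expect_s3_class(cf, "channel_features")
  expect_equal(cf$apen, approximate_entropy(x))
  expect_equal(cf$wpen, wavelet_packet_entropy(x))
  expect_identical(extract_channel_features(x, "emg"), cf)
  # errors carry the channel name
  expect_error(extract_channel_features(rep(0, 64), "sc"), "channel 'sc'")
})
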