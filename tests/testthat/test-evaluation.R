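test_that("accuracy summaries use the N-1 standard deviation", {
  s <- acc_mean_std(c(96, 96, 95, 95, 94, 95, 95, 96, 96, 97))
  expect_equal(s$mean, 95.5)
  expect_equal(s$sd, sqrt(sum((95.5 - s$values)^2) / 9))
  expect_equal(s$n, 10)
  z <- acc_mean_std(rep(88, 10))
  expect_equal(c(z$mean, z$sd), c(88, 0))
  expect_error(acc_mean_std(95), "N >= 2")
  expect_error(acc_mean_std(numeric(0)), "at least one")
  expect_output(print(s), "95.5")
})

test_that("published per-experiment rows reproduce their printed summaries", {
  # every mean +/- sd summary of the reference hold-out tables, at printed
  # precision
  mu <- read.csv(system.file("extdata", "music_holdout_runs.csv",
                             package = "entrofuse"), comment.char = "#")
  printed_music <- list(svm = c(95.5, 0.85), dt = c(90.5, 1.27),
                        elm = c(89.4, 1.78), team = c(98.6, 0.70))
  for (m in names(printed_music)) {
    s <- acc_mean_std(mu[[m]])
    expect_equal(round(s$mean, 1), printed_music[[m]][1])
    expect_equal(round(s$sd, 2), printed_music[[m]][2])
  }

  de <- read.csv(system.file("extdata", "deap_holdout_runs.csv",
                             package = "entrofuse"), comment.char = "#")
  printed_deap <- rbind(
    c(60.3, 1.95), c(61.5, 2.37), c(73.5, 2.07), c(79.5, 1.65),  # s01
    c(53.3, 2.36), c(55.4, 2.37), c(65.1, 2.69), c(70.3, 2.31),  # s02
    c(60.3, 2.00), c(62.9, 1.29), c(81.5, 1.35), c(87.0, 1.05),  # s03
    c(59.4, 2.01), c(50.1, 2.28), c(62.7, 2.21), c(70.0, 1.94),  # s04
    c(52.7, 2.83), c(53.9, 2.73), c(69.2, 2.70), c(75.5, 2.68))  # s05
  for (i in seq_len(nrow(de))) {
    s <- acc_mean_std(as.numeric(de[i, paste0("e", 1:10)]))
    expect_equal(round(s$mean, 1), printed_deap[i, 1])
    expect_equal(round(s$sd, 2), printed_deap[i, 2])
  }
})

test_that("hold-out splits have the protocol sizes and are disjoint", {
  df <- data.frame(label = rep(c("a", "b", "c", "d"), each = 250),
                   f = rnorm(1000))
  df$id <- seq_len(nrow(df))
  parts <- holdout_split(df, experiment_config(train_fraction = 0.8,
                                               subsample_n = 500, seed = 2))
  expect_equal(nrow(parts$train), 400)
  expect_equal(nrow(parts$test), 100)
  expect_length(intersect(parts$train$id, parts$test$id), 0)

  df2 <- df[1:400, ]
  parts2 <- holdout_split(df2, experiment_config(train_fraction = 0.75))
  expect_equal(c(nrow(parts2$train), nrow(parts2$test)), c(300, 100))

  # disjointness and determinism across random configurations
  set.seed(14)
  for (i in 1:100) {
    cfg <- experiment_config(train_fraction = runif(1, 0.5, 0.9),
                             seed = sample(1e6, 1))
    ri <- sample(50, 1)
    p <- holdout_split(df2, cfg, rep_index = ri)
    expect_length(intersect(p$train$id, p$test$id), 0)
    expect_equal(sort(c(p$train$id, p$test$id)), df2$id)
    p2 <- holdout_split(df2, cfg, rep_index = ri)
    expect_identical(p$train$id, p2$train$id)
  }

  # stratification failure: a class too small to appear in both sides
  tiny <- data.frame(label = c(rep("a", 20), "b"), f = rnorm(21))
  expect_error(holdout_split(tiny, experiment_config(train_fraction = 0.8)),
               "absent")
})

test_that("experiments are reproducible and ace separable data", {
  b <- blobs4(n_per = 25, sep = 4, seed = 6)
  df <- data.frame(label = b$y, x1 = b$x[, 1], x2 = b$x[, 2])
  arms <- list(list(features = "fused", classifier = "svm"),
               list(features = "fused", classifier = "dt"),
               list(features = "fused", classifier = "elm"),
               list(features = "fused", classifier = "team"))
  cfg <- experiment_config(train_fraction = 0.8, repetitions = 1, seed = 4)
  rep1 <- run_experiment(df, cfg, arms,
                         fit_args = list(grid = svm_grid(C = 4, gamma = 0.25),
                                         elm_M = 60))
  expect_equal(rep1$runs$acc, rep(100, 4))  # separable sanity

  cfg2 <- experiment_config(repetitions = 2, seed = 9)
  r1 <- run_experiment(df, cfg2, arms[c(1, 4)],
                       fit_args = list(grid = svm_grid(C = 4, gamma = 0.25)))
  r2 <- run_experiment(df, cfg2, arms[c(1, 4)],
                       fit_args = list(grid = svm_grid(C = 4, gamma = 0.25)))
  expect_identical(r1, r2)
  expect_equal(nrow(r1$runs), 4)
  expect_named(r1$summary, c("arm", "features", "classifier", "mean", "sd",
                             "n"))
  # failures carry arm context
  expect_error(
    run_experiment(df, cfg, list(list(features = "nope", classifier = "svm"))),
    "channel 'nope'")
})
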