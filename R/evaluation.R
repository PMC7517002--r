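#' Mean and standard deviation of repeated hold-out accuracies
#'
#' `Acc* = sum(Acc_i) / N` and `sigma = sqrt(sum((Acc* - Acc_i)^2) / (N -
#' 1))` (sample standard deviation), on the percent scale. This is the
#' summary printed as "mean +/- sd" for repeated random train/test splits.
#'
#' @param accs per-repetition accuracies in percent (length >= 2 for the
#'   standard deviation; a single value is an error).
#' @return object of class `"acc_summary"`: list with `mean`, `sd`, `n`,
#'   `values`.
#' @export
acc_mean_std <- function(accs) {
  n <- length(accs)
  if (n < 1) stop("need at least one accuracy value")
  m <- sum(accs) / n
  if (n < 2) stop("need N >= 2 repetitions for the standard deviation")
  s <- sqrt(sum((m - accs)^2) / (n - 1))
  structure(list(mean = m, sd = s, n = n, values = accs),
            class = "acc_summary")
}

#' @export
print.acc_summary <- function(x, digits = 2, ...) {
  cat(sprintf("%.*f ± %.*f  (N = %d)\n",
              max(1, digits - 1), x$mean, digits, x$sd, x$n))
  invisible(x)
}

#' Experiment configuration for repeated hold-out evaluation
#'
#' @param train_fraction fraction of rows used for training (in (0, 1)).
#' @param repetitions number of random splits.
#' @param subsample_n optionally draw this many rows (uniformly, without
#'   replacement, fresh each repetition) before splitting.
#' @param seed base seed; repetition `i` uses a seed derived from
#'   `(seed, i)`.
#' @param stratified preserve class proportions in the split.
#' @export
experiment_config <- function(train_fraction = 0.8, repetitions = 10L,
                              subsample_n = NULL, seed = 1L,
                              stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1, repetitions >= 1)
  structure(list(train_fraction = train_fraction,
                 repetitions = as.integer(repetitions),
                 subsample_n = subsample_n, seed = as.integer(seed),
                 stratified = stratified),
            class = "experiment_config")
}

# Derived per-repetition seed, kept inside the 32-bit integer range.
rep_seed <- function(seed, rep_index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(rep_index) * 104729) %%
               2147483647)
}

#' One deterministic train/test hold-out split
#'
#' Optionally subsamples `cfg$subsample_n` rows first, then splits at
#' `cfg$train_fraction`, stratified by class when `cfg$stratified` (per
#' class, `round(fraction * n_class)` rows go to training). Train and test
#' are disjoint by construction. Deterministic given `(cfg$seed,
#' rep_index)`.
#'
#' @param df feature table with a `label` column.
#' @param cfg an [experiment_config()].
#' @param rep_index repetition number (changes the derived seed).
#' @return list with data.frames `train` and `test`.
#' @export
holdout_split <- function(df, cfg = experiment_config(), rep_index = 1L) {
  stopifnot(nrow(df) > 0, "label" %in% names(df))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rep_seed(cfg$seed, rep_index))
  if (!is.null(cfg$subsample_n)) {
    if (cfg$subsample_n > nrow(df))
      stop("subsample_n exceeds the dataset size")
    df <- df[sample(nrow(df), cfg$subsample_n), , drop = FALSE]
  }
  n <- nrow(df)
  if (cfg$stratified) {
    tr <- unlist(lapply(split(seq_len(n), df$label), function(idx) {
      k <- round(cfg$train_fraction * length(idx))
      if (k == 0 || k == length(idx))
        stop("a class would be absent from the train or test split; ",
             "use more data or stratified = FALSE")
      sample(idx, k)
    }), use.names = FALSE)
  } else {
    tr <- sample(n, round(cfg$train_fraction * n))
  }
  list(train = df[sort(tr), , drop = FALSE],
       test = df[setdiff(seq_len(n), tr), , drop = FALSE])
}

# Columns of one arm's feature view: all feature columns for "fused",
# otherwise the 4 entropy columns of the named channel.
arm_columns <- function(df, features) {
  cols <- feature_columns(df)
  if (identical(features, "fused")) return(cols)
  sub <- cols[startsWith(cols, paste0(features, "."))]
  if (length(sub) == 0) stop("no feature columns for channel '", features, "'")
  sub
}

fit_arm <- function(classifier, x, y, cfg_fit, seed) {
  switch(classifier,
    svm = train_svm(x, y, grid = cfg_fit$grid, cv_folds = cfg_fit$cv_folds,
                    seed = seed),
    dt = train_dt(x, y, epsilon = cfg_fit$epsilon),
    elm = train_elm(x, y, M = cfg_fit$elm_M, seed = seed),
    team = train_team(x, y, grid = cfg_fit$grid, cv_folds = cfg_fit$cv_folds,
                      seed = seed, epsilon = cfg_fit$epsilon,
                      elm_M = cfg_fit$elm_M, cfg = cfg_fit$team_cfg),
    stop("unknown classifier: ", classifier))
}

#' Run a repeated hold-out experiment over arms
#'
#' Each arm pairs a feature view (`"fused"` or a single channel name) with a
#' classifier (`"svm"`, `"dt"`, `"elm"` or `"team"`). For every repetition
#' the table is (optionally) subsampled, split, z-score standardised on the
#' training rows, the arm's model is trained, and test accuracy (percent)
#' is recorded. The whole report is a pure function of `(df, cfg, arms,
#' fit_args)`.
#'
#' @param df feature table from [extract_features()].
#' @param cfg an [experiment_config()].
#' @param arms list of `list(features =, classifier =)` pairs.
#' @param fit_args list of classifier settings: `grid`, `cv_folds`,
#'   `epsilon`, `elm_M`, `team_cfg`.
#' @param scale standardise features (recommended: the RBF-SVM and the ELM
#'   are scale-sensitive).
#' @return list with `runs` (data.frame: arm, features, classifier, rep,
#'   acc) and `summary` (per-arm mean/sd via [acc_mean_std()]).
#' @export
run_experiment <- function(df, cfg = experiment_config(), arms,
                           fit_args = list(), scale = TRUE) {
  stopifnot(length(arms) > 0)
  defaults <- list(grid = svm_grid(), cv_folds = 5, epsilon = 1e-7,
                   elm_M = NULL, team_cfg = referral_config())
  fit_args <- utils::modifyList(defaults, fit_args)
  runs <- list()
  for (rep in seq_len(cfg$repetitions)) {
    parts <- holdout_split(df, cfg, rep)
    for (a in seq_along(arms)) {
      arm <- arms[[a]]
      cols <- arm_columns(df, arm$features)
      sc <- if (scale) fit_scaler(parts$train, cols)
      tr <- if (scale) apply_scaler(parts$train, sc) else parts$train
      te <- if (scale) apply_scaler(parts$test, sc) else parts$test
      xtr <- feature_matrix(tr, cols); ytr <- factor(tr$label)
      xte <- feature_matrix(te, cols)
      model <- tryCatch(
        fit_arm(arm$classifier, xtr, ytr, fit_args,
                seed = rep_seed(cfg$seed, rep)),
        error = function(e) stop(sprintf(
          "arm %d (%s/%s), repetition %d: %s", a, arm$features,
          arm$classifier, rep, conditionMessage(e)), call. = FALSE))
      pred <- predict(model, xte)
      acc <- 100 * mean(pred == te$label)
      runs[[length(runs) + 1L]] <- data.frame(
        arm = a, features = arm$features, classifier = arm$classifier,
        rep = rep, acc = acc, stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$arm), function(r) {
    s <- if (nrow(r) >= 2) acc_mean_std(r$acc) else
      list(mean = mean(r$acc), sd = NA_real_)
    data.frame(arm = r$arm[1L], features = r$features[1L],
               classifier = r$classifier[1L],
               mean = s$mean, sd = s$sd, n = nrow(r),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ, config = cfg)
}
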