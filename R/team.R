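#' Referral thresholds for the team-collaboration strategy
#'
#' The conditional parameters of the margin predicate that flags samples the
#' main SVM is likely to misclassify. Defaults `t1 = 1.5`, `t2 = 3.0`.
#'
#' @param t1,t2 positive reals.
#' @export
referral_config <- function(t1 = 1.5, t2 = 3.0) {
  stopifnot(t1 > 0, t2 > 0)
  structure(list(t1 = t1, t2 = t2), class = "referral_config")
}

#' Margin summary of a one-vs-one decision
#'
#' For a 4-class OvO vote the winner is involved in three pairwise machines
#' and the runner-up in three as well. `u_min`/`h_max` are the smallest and
#' largest absolute decision values among the machines involving the
#' top-voted class; `v_min`/`s_max` the same for the second-ranked class
#' (taken over that class's machines regardless of its vote count; ranking
#' ties are resolved by the signed decision-value sum).
#'
#' @param pd a [pairwise_decision()].
#' @return object of class `"margin_summary"`: list with `u_min`, `h_max`,
#'   `v_min`, `s_max`, `top`, `second`.
#' @export
margin_summary <- function(pd) {
  stopifnot(inherits(pd, "pairwise_decision"))
  top <- pd$ranking[1L]
  second <- pd$ranking[2L]
  in_top <- pd$pair_i == top | pd$pair_j == top
  in_second <- pd$pair_i == second | pd$pair_j == second
  a_top <- abs(pd$f[in_top])
  a_sec <- abs(pd$f[in_second])
  structure(list(u_min = min(a_top), h_max = max(a_top),
                 v_min = min(a_sec), s_max = max(a_sec),
                 top = top, second = second),
            class = "margin_summary")
}

#' Should a sample be referred to the auxiliary classifiers?
#'
#' A sample is flagged for referral (re-diagnosis by the decision tree and
#' the ELM) when either
#' * the highest vote count is tied between classes, or
#' * the margin predicate holds: `u_min > v_min` and
#'   `h_max * u_min > s_max * v_min` and `t1 < h_max * v_min` and
#'   `u_min * s_max < t2`,
#' with the quantities of [margin_summary()]. A full-vote winner for which
#' the predicate is false is outside the set conditions and the SVM decides
#' alone.
#'
#' @param pd a [pairwise_decision()].
#' @param cfg a [referral_config()].
#' @return logical scalar.
#' @export
is_referral <- function(pd, cfg = referral_config()) {
  if (sum(pd$votes == max(pd$votes)) > 1L) return(TRUE)  # tied top votes
  referral_predicate(margin_summary(pd), cfg)
}

# The four-inequality margin predicate of the referral condition, isolated
# so alternative readings of the (typographically ambiguous) conjunction can
# be swapped in one place.
referral_predicate <- function(ms, cfg) {
  ms$u_min > ms$v_min &&
    ms$h_max * ms$u_min > ms$s_max * ms$v_min &&
    cfg$t1 < ms$h_max * ms$v_min &&
    ms$u_min * ms$s_max < cfg$t2
}

#' Arbitrate one sample under the team decision principles
#'
#' * Principle I: the sample is not referred; the SVM's top-voted class is
#'   final.
#' * Principle II: the sample is referred and at least one of the tree/ELM
#'   agrees with the SVM's top class; majority rules and the top class is
#'   final.
#' * Principle III: both auxiliaries disagree with the top class and at
#'   least one matches the SVM's second-ranked class; the second-ranked
#'   class is final.
#' * FALLBACK: referred but neither II nor III applies; the SVM's top class
#'   is kept (a case the decision principles do not cover).
#'
#' @param pd a [pairwise_decision()] for the sample.
#' @param dt_label,elm_label auxiliary classifier labels for the sample.
#' @param cfg a [referral_config()].
#' @param referral `"auto"` evaluates [is_referral()]; `"always"`/`"never"`
#'   force the referral flag (useful for ablations).
#' @return object of class `"team_verdict"`: list with `label`, `principle`
#'   (`"I"`, `"II"`, `"III"` or `"FALLBACK"`), `referred`, `svm_top`,
#'   `svm_second`, `dt`, `elm`, `margins`.
#' @export
team_decide <- function(pd, dt_label, elm_label, cfg = referral_config(),
                        referral = c("auto", "always", "never")) {
  referral <- match.arg(referral)
  if (!all(c(dt_label, elm_label) %in% pd$classes))
    stop("auxiliary label outside the model's class set")
  ms <- margin_summary(pd)
  top <- ms$top; second <- ms$second
  referred <- switch(referral, auto = is_referral(pd, cfg),
                     always = TRUE, never = FALSE)
  if (!referred) {
    label <- top; principle <- "I"
  } else if (dt_label == top || elm_label == top) {
    label <- top; principle <- "II"
  } else if (dt_label == second || elm_label == second) {
    label <- second; principle <- "III"
  } else {
    label <- top; principle <- "FALLBACK"
  }
  structure(list(label = label, principle = principle, referred = referred,
                 svm_top = top, svm_second = second,
                 dt = dt_label, elm = elm_label, margins = ms),
            class = "team_verdict")
}

#' Train the full SVM-DT-ELM team
#'
#' Convenience wrapper fitting the three base learners on the same training
#' matrix.
#'
#' @inheritParams train_svm
#' @param epsilon decision-tree stop threshold, see [train_dt()].
#' @param elm_M,elm_activation ELM hidden size and activation, see
#'   [train_elm()].
#' @param cfg default [referral_config()] stored with the model.
#' @return object of class `"team_model"` with elements `svm`, `dt`, `elm`,
#'   `cfg`.
#' @export
train_team <- function(x, y, grid = svm_grid(), cv_folds = 5, seed = 1,
                       epsilon = 1e-7, elm_M = NULL,
                       elm_activation = "sigmoid",
                       cfg = referral_config()) {
  x <- as.matrix(x)
  structure(list(
    svm = train_svm(x, y, grid = grid, cv_folds = cv_folds, seed = seed),
    dt = train_dt(x, y, epsilon = epsilon),
    elm = train_elm(x, y, M = elm_M, seed = seed,
                    activation = elm_activation),
    cfg = cfg), class = "team_model")
}

#' Classify a batch with the team-collaboration strategy
#'
#' Runs the OvO SVM on every row, computes vote margins, refers flagged
#' samples to the tree and the ELM, and applies the decision principles of
#' [team_decide()]. The returned data frame carries one row per sample with
#' the final label, the principle that fired, the component labels and the
#' margin quantities; `attr(result, "principle_counts")` tabulates the
#' principles (summing to the batch size).
#'
#' @param models a `"team_model"` from [train_team()] (or a list with
#'   elements `svm`, `dt`, `elm`).
#' @param x feature matrix or feature table rows to classify.
#' @param cfg a [referral_config()]; defaults to the model's.
#' @param referral referral mode passed to [team_decide()].
#' @return data.frame with columns `label`, `principle`, `referred`,
#'   `svm_top`, `svm_second`, `dt`, `elm`, `u_min`, `h_max`, `v_min`,
#'   `s_max`.
#' @export
classify_batch <- function(models, x, cfg = NULL,
                           referral = c("auto", "always", "never")) {
  referral <- match.arg(referral)
  if (is.null(cfg)) cfg <- models$cfg %||% referral_config()
  X <- if (is.data.frame(x)) feature_matrix(x) else as.matrix(x)
  if (ncol(X) != models$svm$n_features)
    stop("feature-space mismatch between models and data")
  F <- svm_decision_matrix(models$svm, X)
  dt_lab <- predict(models$dt, X)
  elm_lab <- predict(models$elm, X)
  verdicts <- lapply(seq_len(nrow(X)), function(i) {
    pd <- pairwise_decision(models$svm$classes, models$svm$pairs$pair_i,
                            models$svm$pairs$pair_j, F[i, ])
    team_decide(pd, dt_lab[i], elm_lab[i], cfg, referral = referral)
  })
  out <- data.frame(
    label = vapply(verdicts, `[[`, character(1), "label"),
    principle = vapply(verdicts, `[[`, character(1), "principle"),
    referred = vapply(verdicts, `[[`, logical(1), "referred"),
    svm_top = vapply(verdicts, `[[`, character(1), "svm_top"),
    svm_second = vapply(verdicts, `[[`, character(1), "svm_second"),
    dt = dt_lab, elm = elm_lab,
    u_min = vapply(verdicts, function(v) v$margins$u_min, numeric(1)),
    h_max = vapply(verdicts, function(v) v$margins$h_max, numeric(1)),
    v_min = vapply(verdicts, function(v) v$margins$v_min, numeric(1)),
    s_max = vapply(verdicts, function(v) v$margins$s_max, numeric(1)),
    stringsAsFactors = FALSE)
  attr(out, "principle_counts") <- table(factor(
    out$principle, levels = c("I", "II", "III", "FALLBACK")))
  out
}

#' @export
predict.team_model <- function(object, newdata, cfg = NULL, ...) {
  classify_batch(object, newdata, cfg = cfg)$label
}

`%||%` <- function(a, b) if (is.null(a)) b else a
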