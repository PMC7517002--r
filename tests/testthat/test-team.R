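# Build a 4-class decision where `top` wins all its pairs (|f| = u_f) and
# `second` wins its remaining pairs (|f| = v_f).
make_pd <- function(top, second, u_f = 2, v_f = 1,
                    classes = c("A", "B", "C", "D")) {
  pairs <- combn(classes, 2)
  f <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    f[p] <- if (i == top) u_f else if (j == top) -u_f
            else if (i == second) v_f else if (j == second) -v_f
            else 0.1
  }
  pairwise_decision(classes, pairs[1, ], pairs[2, ], f)
}

test_that("margin summary extracts the winner and runner-up extremes", {
  # top class A with |f| {0.4, 1.2, 2.0}; runner-up B with {0.4, 0.5, 0.6}
  pd <- pd4(c(0.4, 1.2, 2.0, 0.5, 0.6, 0.3))
  expect_equal(pd$ranking[1:2], c("A", "B"))
  ms <- margin_summary(pd)
  expect_equal(ms$u_min, 0.4)
  expect_equal(ms$h_max, 2.0)
  expect_equal(ms$v_min, 0.4)  # pair AB belongs to both classes' machines
  expect_equal(ms$s_max, 0.6)

  # degenerate: all |f| equal
  ms1 <- margin_summary(pd4(c(1, 1, 1, 1, 1, -1)))
  expect_equal(unlist(ms1[c("u_min", "h_max", "v_min", "s_max")]),
               c(u_min = 1, h_max = 1, v_min = 1, s_max = 1))

  set.seed(55)
  for (i in 1:1000) {
    ms <- margin_summary(pd4())
    expect_lte(ms$u_min, ms$h_max)
    expect_lte(ms$v_min, ms$s_max)
    expect_gte(ms$u_min, 0)
  }
})

test_that("referral fires on vote ties and on the margin predicate", {
  # tied top votes trigger referral; with 4 classes the tie is a vote cycle
  # (A > B,C; B > C,D is impossible -- the achievable top tie is 2-2-2)
  pairs <- combn(c("A", "B", "C", "D"), 2)  # AB AC AD BC BD CD
  tie <- pairwise_decision(c("A", "B", "C", "D"), pairs[1, ], pairs[2, ],
                           c(1, 1, -1, 1, 1, -1))  # A,B,D each take 2 votes
  expect_equal(sort(unname(tie$votes), decreasing = TRUE)[1:2], c(2L, 2L))
  expect_true(is_referral(tie))

  # predicate arithmetic, default t1 = 1.5, t2 = 3
  prd <- entrofuse:::referral_predicate
  cfg <- referral_config()
  expect_false(prd(list(u_min = 2, h_max = 3, v_min = 0.1, s_max = 0.2),
                   cfg))  # t1 < h_max * v_min = 0.3 fails -> SVM decides
  expect_true(prd(list(u_min = 1, h_max = 2, v_min = 0.9, s_max = 1.1),
                  cfg))   # all four inequalities hold
  # through a full decision object: strong unambiguous winner, no referral
  expect_false(is_referral(make_pd("A", "B", u_f = 3, v_f = 0.1)))
})

test_that("team decisions follow principles I-III with exhaustive oracle", {
  classes <- c("A", "B", "C", "D")
  # spot checks mirroring the worked cases
  pd <- make_pd("A", "B")
  expect_equal(team_decide(pd, "C", "D", referral = "never")$principle, "I")
  expect_equal(team_decide(pd, "C", "D", referral = "never")$label, "A")
  v2 <- team_decide(pd, "A", "C", referral = "always")
  expect_equal(c(v2$label, v2$principle), c("A", "II"))
  v3 <- team_decide(pd, "B", "C", referral = "always")
  expect_equal(c(v3$label, v3$principle), c("B", "III"))

  # exhaustive 4^3 combinations x referred/not against the hand oracle
  for (top in classes) {
    second <- classes[classes != top][1]
    pd <- make_pd(top, second)
    expect_equal(pd$ranking[1:2], c(top, second))
    for (dt in classes) for (elm in classes) {
      for (ref in c(TRUE, FALSE)) {
        got <- team_decide(pd, dt, elm,
                           referral = if (ref) "always" else "never")
        want <- team_oracle(ref, top, second, dt, elm)
        expect_equal(got$label, want$label)
        expect_equal(got$principle, want$principle)
      }
    }
  }
  expect_error(team_decide(pd, "Z", "A"), "class set")
})

test_that("batch classification degenerates to the SVM when nothing refers", {
  b <- blobs4(n_per = 15, sep = 4, seed = 8)
  team <- train_team(b$x, b$y, grid = svm_grid(C = 4, gamma = 0.25),
                     elm_M = 40, seed = 2)
  noref <- classify_batch(team, b$x, referral = "never")
  expect_equal(noref$label, unname(predict(team$svm, b$x)))
  expect_true(all(noref$principle == "I"))

  # forced referral: arbitration fully determined by principles II/III/fallback
  allref <- classify_batch(team, b$x, referral = "always")
  for (i in seq_len(nrow(allref))) {
    want <- team_oracle(TRUE, allref$svm_top[i], allref$svm_second[i],
                        allref$dt[i], allref$elm[i])
    expect_equal(allref$label[i], want$label)
    expect_equal(allref$principle[i], want$principle)
  }
  expect_false(any(allref$principle == "I"))

  # principle tally always sums to the batch size
  auto <- classify_batch(team, b$x)
  expect_equal(sum(attr(auto, "principle_counts")), nrow(b$x))
  expect_error(classify_batch(team, b$x[, 1, drop = FALSE]), "mismatch")
})
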