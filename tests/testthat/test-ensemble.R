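# small helpers building prediction fixtures in code
two_binary_models <- function() {
  probs <- array(0, c(2, 1, 2))
  probs[1, 1, ] <- c(0.6, 0.4)
  probs[2, 1, ] <- c(0.2, 0.8)
  prediction_set(probs)
}

# binary-exact probabilities, so weighted ties are exact in floating point
two_binary_models_exact <- function() {
  probs <- array(0, c(2, 1, 2))
  probs[1, 1, ] <- c(0.625, 0.375)
  probs[2, 1, ] <- c(0.125, 0.875)
  prediction_set(probs)
}

test_that("prediction sets validate probability rows", {
  bad <- array(0.6, c(2, 3, 2))
  expect_error(prediction_set(bad), "sum to 1")
  expect_error(prediction_set(array(1, c(1, 2))), "array")
})

test_that("soft voting averages rows with the stated tie rule", {
  P <- two_binary_models()
  out <- soft_vote(P)
  expect_equal(out$probs[1, ], c(0.4, 0.6))
  expect_equal(out$labels, 1L)
  # identical models reproduce any single model
  probs <- array(rep(c(0.3, 0.7), each = 3), c(3, 1, 2))
  same <- prediction_set(aperm(array(c(0.3, 0.7, 0.3, 0.7, 0.3, 0.7),
                                     c(2, 1, 3)), c(3, 2, 1)))
  out2 <- soft_vote(same)
  expect_equal(out2$probs[1, ], c(0.3, 0.7))
  # exact two-way tie goes to class 0
  tie <- array(0.5, c(2, 1, 2))
  expect_equal(soft_vote(prediction_set(tie))$labels, 0L)
})

test_that("hard voting takes the majority, ties to the smallest index", {
  mk <- function(votes, K) {
    probs <- array(1 / K, c(length(votes), 2, K))
    for (m in seq_along(votes)) {
      row <- rep(0.1 / (K - 1) * (K - 1), K)
      row <- rep((1 - 0.9) / (K - 1), K)
      row[votes[m] + 1] <- 0.9
      row <- row / sum(row)
      probs[m, 1, ] <- row
      probs[m, 2, ] <- row
    }
    prediction_set(probs)
  }
  expect_equal(hard_vote(mk(c(1, 1, 2), 3))[1], 1L)
  expect_equal(hard_vote(mk(c(0, 0, 1, 1), 2))[1], 0L) # 2-2 split -> 0
  expect_equal(hard_vote(mk(c(2, 2, 2), 3))[1], 2L)
})

test_that("weighted averaging generalizes soft voting", {
  P <- two_binary_models()
  # one-hot weights reproduce that model
  expect_equal(weighted_average(P, c(1, 0))$probs[1, ], c(0.6, 0.4))
  # uniform weights match soft_vote exactly
  expect_identical(weighted_average(P, c(0.5, 0.5))$probs, soft_vote(P)$probs)
  # hand-computed combination: 0.75 * (0.6, 0.4) + 0.25 * (0.2, 0.8)
  out <- weighted_average(P, c(0.75, 0.25))
  expect_equal(out$probs[1, ], c(0.5, 0.5))
  # exact tie (binary-exact inputs) breaks to class 0
  out_exact <- weighted_average(two_binary_models_exact(), c(0.75, 0.25))
  expect_identical(out_exact$probs[1, ], c(0.5, 0.5))
  expect_equal(out_exact$labels, 0L)
  expect_error(weighted_average(P, c(1, 0, 0)), "one weight per model")
})

test_that("weight normalization clips, rescales and handles degeneracy", {
  expect_equal(normalize_weights(c(2, 2)), c(0.5, 0.5))
  expect_equal(normalize_weights(c(-1, 3)), c(0, 1))
  expect_equal(normalize_weights(c(0, 0)), c(0.5, 0.5))
  expect_equal(sum(normalize_weights(runif(7))), 1)
  expect_error(normalize_weights(c(1, NA)), "finite")
})

test_that("optimized weights favor a dominant model and dominate singles", {
  for (seed in c(2, 5, 9, 13, 17)) {
    gp <- gen_predictions(n_models = 3, n_samples = 400, n_classes = 3,
                          accuracies = c(0.95, 0.55, 0.55),
                          correlation = 0.1, seed = seed)
    ow <- optimize_weights(gp$predictions, gp$labels, seed = seed)
    expect_equal(which.max(ow$weights), 1L)
    expect_equal(sum(ow$weights), 1, tolerance = 1e-9)
  }
  # accuracy objective: fused validation accuracy >= best single model
  gp <- gen_predictions(n_models = 4, n_samples = 600, n_classes = 3,
                        accuracies = c(0.7, 0.8, 0.85, 0.9),
                        correlation = 0.3, seed = 3)
  singles <- vapply(1:4, function(m) {
    mean(max.col(matrix(gp$predictions$probs[m, , ], 600),
                 "first") - 1L == gp$labels)
  }, numeric(1))
  ow <- optimize_weights(gp$predictions, gp$labels, objective = "accuracy",
                         seed = 11)
  fused <- weighted_average(gp$predictions, ow$weights)
  expect_gte(mean(fused$labels == gp$labels), max(singles))
})

test_that("identical models make the optimized ensemble equal any single", {
  probs <- array(0, c(3, 50, 2))
  set.seed(4)
  base <- runif(50, 0.1, 0.9)
  for (m in 1:3) probs[m, , ] <- cbind(base, 1 - base)
  y <- as.integer(base < 0.5)
  ow <- optimize_weights(prediction_set(probs), y, seed = 6)
  fused <- weighted_average(prediction_set(probs), ow$weights)
  expect_equal(fused$probs, cbind(base, 1 - base), ignore_attr = TRUE)
})

test_that("boosting reproduces a hand-executed two-round fixture", {
  # 4 samples, binary; model 1 errs on sample 4, model 2 errs on sample 1
  probs <- array(0, c(2, 4, 2))
  m1 <- c(0, 0, 1, 0) # predicted labels
  m2 <- c(1, 0, 1, 1)
  for (i in 1:4) {
    probs[1, i, ] <- if (m1[i] == 0) c(0.9, 0.1) else c(0.1, 0.9)
    probs[2, i, ] <- if (m2[i] == 0) c(0.9, 0.1) else c(0.1, 0.9)
  }
  y <- c(0, 0, 1, 1)
  out <- boost_ensemble(prediction_set(probs), y, rounds = 2)
  # round 1: both models have weighted error 1/4; tie -> model 1,
  # alpha = ln(3). Sample 4 is up-weighted to 1/2.
  # round 2: model 1 error 1/2 (at the chance bound), model 2 error 1/6
  # -> model 2 selected, alpha = ln(5).
  expect_equal(out$rounds$model, c(1, 2))
  expect_equal(out$rounds$err, c(0.25, 1 / 6))
  expect_equal(out$rounds$alpha, c(log(3), log(5)))
  # fused weighted vote: model 2 outweighs model 1 where they disagree
  expect_equal(out$labels, c(1L, 0L, 1L, 1L))
})

test_that("a perfect model is selected once and reproduces itself", {
  probs <- array(0, c(2, 6, 2))
  y <- c(0, 0, 0, 1, 1, 1)
  for (i in 1:6) {
    probs[1, i, ] <- if (y[i] == 0) c(0.95, 0.05) else c(0.05, 0.95)
    probs[2, i, ] <- c(0.5 + 1e-3 * (i %% 2), 0.5 - 1e-3 * (i %% 2))
  }
  out <- boost_ensemble(prediction_set(probs), y, rounds = 3)
  expect_equal(out$rounds$model[1], 1)
  expect_equal(out$rounds$err[1], 0)
  expect_true(is.finite(out$rounds$alpha[1]))
  expect_equal(out$labels, y)
  expect_error(boost_ensemble(prediction_set(probs), rep(0L, 6)),
               "two classes")
})

test_that("stacking learns a separable fixture and degrades gracefully", {
  gp <- gen_predictions(n_models = 1, n_samples = 200, n_classes = 3,
                        accuracies = 1.0, correlation = 0, seed = 2)
  out <- stack_ensemble(gp$predictions, gp$labels, gp$predictions)
  expect_equal(mean(out$labels == gp$labels), 1.0)
  # zero iterations: zero-init softmax is uniform, all ties resolve to 0
  out0 <- stack_ensemble(gp$predictions, gp$labels, gp$predictions,
                         iters = 0L)
  expect_true(all(out0$labels == 0L))
  expect_true(all(abs(out0$probs - 1 / 3) < 1e-12))
  # deterministic
  out2 <- stack_ensemble(gp$predictions, gp$labels, gp$predictions)
  expect_identical(out$probs, out2$probs)
})

test_that("blending mirrors stacking on a seeded validation split", {
  gp <- gen_predictions(n_models = 2, n_samples = 300, n_classes = 2,
                        accuracies = c(0.9, 0.8), correlation = 0.2, seed = 5)
  out <- blend_ensemble(gp$predictions, gp$labels, gp$predictions,
                        split_fraction = 0.5, seed = 3)
  expect_length(out$holdout_idx, 150)
  expect_gt(mean(out$labels == gp$labels), 0.8)
  out2 <- blend_ensemble(gp$predictions, gp$labels, gp$predictions,
                         split_fraction = 0.5, seed = 3)
  expect_identical(out$labels, out2$labels)
  expect_error(blend_ensemble(gp$predictions, gp$labels, gp$predictions,
                              split_fraction = 1.5), "strictly between")
  expect_error(blend_ensemble(gp$predictions, gp$labels, gp$predictions,
                              split_fraction = 0.005), "fewer samples")
})

test_that("bagging weights follow bootstrap accuracies", {
  gp <- gen_predictions(n_models = 3, n_samples = 500, n_classes = 3,
                        accuracies = c(0.9, 0.7, 0.5), correlation = 0,
                        seed = 8)
  out <- bag_ensemble(gp$predictions, gp$labels, B = 25, seed = 2)
  expect_equal(sum(out$weights), 1, tolerance = 1e-9)
  expect_equal(order(out$weights, decreasing = TRUE), c(1, 2, 3))
  # B = 1 identity-free check: weights proportional to resample accuracies
  out1 <- bag_ensemble(gp$predictions, gp$labels, B = 1, seed = 4)
  expect_equal(sum(out1$weights), 1, tolerance = 1e-9)
  # identical models get uniform weights
  probs <- array(rep(gp$predictions$probs[1, , ], each = 3), c(3, 500, 3))
  outu <- bag_ensemble(prediction_set(probs), gp$labels, B = 10, seed = 5)
  expect_equal(outu$weights, rep(1 / 3, 3))
  # reproducibility
  expect_identical(bag_ensemble(gp$predictions, gp$labels, B = 10,
                                seed = 9)$weights,
                   bag_ensemble(gp$predictions, gp$labels, B = 10,
                                seed = 9)$weights)
})

test_that("the hybrid combiner majority-votes ensemble outputs", {
  expect_equal(hybrid_vote(list(c(1L, 0L), c(1L, 0L), c(1L, 1L))), c(1L, 0L))
  expect_equal(hybrid_vote(list(c(0L), c(0L), c(1L))), 0L)
  expect_equal(hybrid_vote(list(c(0L, 2L), c(1L, 2L))), c(0L, 2L)) # tie -> 0
  expect_error(hybrid_vote(list(c(0L, 1L), c(0L))), "one length")
  expect_error(hybrid_vote(list()), "at least one")
})

test_that("fused probabilities stay on the simplex and are permutation-safe", {
  gp <- gen_predictions(n_models = 4, n_samples = 100, n_classes = 4,
                        accuracies = c(0.6, 0.7, 0.8, 0.9),
                        correlation = 0.2, seed = 14)
  P <- gp$predictions
  for (out in list(soft_vote(P), weighted_average(P, c(0.1, 0.2, 0.3, 0.4)))) {
    expect_true(all(out$probs >= 0))
    expect_true(all(abs(rowSums(out$probs) - 1) < 1e-6))
  }
  # permuting the model order permutes bagging weights identically and
  # leaves the fused labels unchanged
  perm <- c(3, 1, 4, 2)
  P_perm <- prediction_set(P$probs[perm, , , drop = FALSE])
  b1 <- bag_ensemble(P, gp$labels, B = 15, seed = 7)
  b2 <- bag_ensemble(P_perm, gp$labels, B = 15, seed = 7)
  expect_equal(b2$weights, b1$weights[perm], tolerance = 1e-12)
  expect_equal(b2$labels, b1$labels)
})
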