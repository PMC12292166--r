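# Fusion strategies over the class-probability outputs of several fixed
# base models (here: the per-resolution stage models of the progressive
# workflow): soft/hard voting, simplex-weighted averaging (with
# DCWOA-optimized weights), bagging, boosting over the fixed pool,
# stacking, blending, and a hybrid majority combiner.
#
# Conventions: probabilities live in an n_models x n_samples x n_classes
# array; labels are 0-based; every argmax tie breaks to the smallest class
# index.

#' Bundle per-model class probabilities
#'
#' @param probs `n_models x n_samples x n_classes` array; every per-sample
#'   row must be a probability vector (non-negative, summing to 1 within
#'   1e-6).
#' @param model_ids Optional model labels (default `model_1`, ...).
#' @param class_labels Optional class labels (default `class_0`, ...).
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(probs, model_ids = NULL, class_labels = NULL) {
  if (length(dim(probs)) != 3L) {
    stop("probs must be an n_models x n_samples x n_classes array")
  }
  if (dim(probs)[1] < 1) stop("need at least one model")
  sums <- apply(probs, c(1, 2), sum)
  if (any(probs < -1e-9) || any(abs(sums - 1) > 1e-6)) {
    stop("every per-sample probability row must be non-negative and sum to 1")
  }
  if (is.null(model_ids)) model_ids <- paste0("model_", seq_len(dim(probs)[1]))
  if (is.null(class_labels)) {
    class_labels <- paste0("class_", seq_len(dim(probs)[3]) - 1L)
  }
  stopifnot(length(model_ids) == dim(probs)[1],
            length(class_labels) == dim(probs)[3])
  structure(list(probs = probs, model_ids = model_ids,
                 class_labels = class_labels),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  d <- dim(x$probs)
  cat("<prediction_set>", d[1], "models x", d[2], "samples x", d[3],
      "classes\n")
  invisible(x)
}

n_models <- function(P) dim(P$probs)[1]
n_samples <- function(P) dim(P$probs)[2]
n_classes <- function(P) dim(P$probs)[3]

# argmax with ties to the smallest class index; returns 0-based labels
argmax_labels <- function(prob_matrix) {
  max.col(prob_matrix, ties.method = "first") - 1L
}

model_probs <- function(P, m) {
  matrix(P$probs[m, , ], nrow = n_samples(P))
}

#' Soft voting
#'
#' Unweighted mean of the per-model probability rows; the label is the
#' argmax (ties to the smallest class index). Computed as
#' [weighted_average()] with uniform weights, so the two agree exactly.
#'
#' @param P A [prediction_set()].
#' @return List with `probs` (`n_samples x n_classes`) and `labels`
#'   (0-based).
#' @export
soft_vote <- function(P) {
  stopifnot(inherits(P, "prediction_set"))
  weighted_average(P, rep(1 / n_models(P), n_models(P)))
}

#' Hard (majority) voting
#'
#' Majority over per-model argmax labels; all ties break to the smallest
#' class index (both inside each model's argmax and in the vote count).
#'
#' @param P A [prediction_set()].
#' @return Integer vector of fused 0-based labels.
#' @export
hard_vote <- function(P) {
  stopifnot(inherits(P, "prediction_set"))
  K <- n_classes(P)
  votes <- vapply(seq_len(n_models(P)),
                  function(m) argmax_labels(model_probs(P, m)),
                  integer(n_samples(P)))
  votes <- matrix(votes, nrow = n_samples(P))
  apply(votes, 1, function(v) {
    counts <- tabulate(v + 1L, nbins = K)
    which.max(counts) - 1L
  })
}

#' Normalize raw weights onto the simplex
#'
#' Negatives are clipped to zero, then the vector is divided by its sum; an
#' all-zero vector (after clipping) falls back to uniform weights.
#'
#' @param raw Finite numeric vector.
#' @return Simplex weight vector (non-negative, summing to 1).
#' @export
normalize_weights <- function(raw) {
  if (!all(is.finite(raw))) stop("weights must be finite")
  w <- pmax(raw, 0)
  s <- sum(w)
  if (s == 0) rep(1 / length(w), length(w)) else w / s
}

#' Weighted model averaging
#'
#' Convex combination of the per-model probability rows with simplex
#' weights; uniform weights reproduce [soft_vote()] exactly.
#'
#' @param P A [prediction_set()].
#' @param w Simplex weight vector, one weight per model.
#' @return List with `probs` and `labels`.
#' @export
weighted_average <- function(P, w) {
  stopifnot(inherits(P, "prediction_set"))
  if (length(w) != n_models(P)) {
    stop("need one weight per model (", n_models(P), "), got ", length(w))
  }
  probs <- matrix(0, n_samples(P), n_classes(P))
  for (m in seq_len(n_models(P))) {
    probs <- probs + w[m] * model_probs(P, m)
  }
  list(probs = probs, labels = argmax_labels(probs))
}

ensemble_cross_entropy <- function(P, w, y) {
  probs <- weighted_average(P, normalize_weights(w))$probs
  p_true <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p_true, 1e-12)))
}

ensemble_error_rate <- function(P, w, y) {
  labels <- weighted_average(P, normalize_weights(w))$labels
  mean(labels != y)
}

#' Optimize ensemble weights with DCWOA
#'
#' Searches raw weight vectors in `[0, 1]^n_models` (normalized onto the
#' simplex inside the objective) with the dynamic chaotic whale optimizer.
#' The initial population is seeded with all one-hot vectors plus the
#' uniform vector, so with the accuracy objective the returned ensemble can
#' never score below the best single model on the validation data
#' (elitism keeps the best seed).
#'
#' @param P_val Validation [prediction_set()].
#' @param y_val Validation labels (0-based).
#' @param objective `"cross_entropy"` (smooth, default) or `"accuracy"`.
#' @param config Optional [woa_config()] override; dimension and bounds are
#'   set from the model count when `NULL`.
#' @param seed Seed used when `config` is `NULL`.
#' @return List with `weights` (simplex vector), `fitness`, and the
#'   optimizer `result`.
#' @export
optimize_weights <- function(P_val, y_val,
                             objective = c("cross_entropy", "accuracy"),
                             config = NULL, seed = NULL) {
  stopifnot(inherits(P_val, "prediction_set"))
  objective <- match.arg(objective)
  M <- n_models(P_val)
  if (length(y_val) != n_samples(P_val)) {
    stop("y_val length must match the prediction set")
  }
  seeds <- rbind(diag(M), rep(1 / M, M))
  if (is.null(config)) {
    config <- woa_config("dcwoa", dimension = M, bounds = c(0, 1),
                         population_size = max(10L, nrow(seeds)),
                         max_iters = 20L, seed = seed,
                         init_population = seeds)
  } else if (is.null(config$init_population)) {
    if (config$population_size < nrow(seeds)) {
      stop("population_size too small for the one-hot + uniform seeding (need >= ",
           nrow(seeds), ")")
    }
    config$init_population <- seeds
  }
  obj <- switch(objective,
                cross_entropy = function(w) ensemble_cross_entropy(P_val, w, y_val),
                accuracy = function(w) ensemble_error_rate(P_val, w, y_val))
  res <- woa_run(obj, config)
  list(weights = normalize_weights(res$best_position),
       fitness = res$best_fitness,
       result = res)
}

#' Bootstrap-weighted averaging (bagging over a fixed pool)
#'
#' Draws `B` seeded bootstrap resamples of the validation set; on each,
#' every model's accuracy is computed and normalized into a weight vector.
#' The final weights are the mean of the `B` vectors and fusion is
#' [weighted_average()].
#'
#' @param P_val Validation [prediction_set()].
#' @param y_val Validation labels.
#' @param B Number of bootstrap resamples (default 20).
#' @param seed RNG seed for the resamples.
#' @param P_apply Prediction set to fuse (defaults to `P_val`).
#' @return List with `weights`, `probs`, `labels`.
#' @export
bag_ensemble <- function(P_val, y_val, B = 20L, seed = 1L, P_apply = P_val) {
  stopifnot(inherits(P_val, "prediction_set"), B >= 1)
  set.seed(seed)
  n <- n_samples(P_val)
  model_labels <- vapply(seq_len(n_models(P_val)),
                         function(m) argmax_labels(model_probs(P_val, m)),
                         integer(n))
  model_labels <- matrix(model_labels, nrow = n)
  wmat <- t(vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    acc <- colMeans(model_labels[idx, , drop = FALSE] == y_val[idx])
    normalize_weights(acc)
  }, numeric(n_models(P_val))))
  w <- colMeans(wmat)
  fused <- weighted_average(P_apply, w)
  c(list(weights = w), fused)
}

#' Adaptive boosting over a fixed model pool
#'
#' Multi-class adaptive boosting where the "weak learners" are the fixed
#' base models: each round selects the model with the lowest weighted error
#' on the validation labels, gives it weight
#' `log((1 - err) / err) + log(K - 1)` (error floored at 1e-10 so a perfect
#' model gets a large finite weight), multiplicatively up-weights the
#' samples it misclassified, and renormalizes. Models may be selected
#' repeatedly; selection stops early if even the best model's weighted
#' error reaches `(K - 1) / K` (no better than chance).
#'
#' @param P_val Validation [prediction_set()].
#' @param y_val Validation labels; must contain at least two classes.
#' @param rounds Maximum boosting rounds.
#' @param P_apply Prediction set to fuse with the learned round weights
#'   (defaults to `P_val`).
#' @return List with `rounds` (data frame: round, model, err, alpha),
#'   `model_weights` (summed alpha per model), and fused `labels`.
#' @export
boost_ensemble <- function(P_val, y_val, rounds = 10L, P_apply = P_val) {
  stopifnot(inherits(P_val, "prediction_set"), rounds >= 1)
  K <- n_classes(P_val)
  if (length(unique(y_val)) < 2) {
    stop("boosting needs at least two classes in y_val")
  }
  n <- n_samples(P_val)
  M <- n_models(P_val)
  model_labels <- vapply(seq_len(M),
                         function(m) argmax_labels(model_probs(P_val, m)),
                         integer(n))
  model_labels <- matrix(model_labels, nrow = n)
  miss <- model_labels != y_val # n x M
  w <- rep(1 / n, n)
  eps <- 1e-10
  log_rounds <- data.frame(round = integer(0), model = integer(0),
                           err = numeric(0), alpha = numeric(0))
  for (b in seq_len(rounds)) {
    errs <- colSums(w * miss)
    m_star <- which.min(errs)
    err <- errs[m_star]
    if (err >= (K - 1) / K) break
    err_f <- min(max(err, eps), 1 - eps)
    alpha <- log((1 - err_f) / err_f) + log(K - 1)
    log_rounds <- rbind(log_rounds,
                        data.frame(round = b, model = m_star, err = err,
                                   alpha = alpha))
    w <- w * exp(alpha * miss[, m_star])
    w <- w / sum(w)
  }
  if (nrow(log_rounds) == 0) {
    stop("no model beat chance on the weighted validation sample")
  }
  model_weights <- vapply(seq_len(M), function(m) {
    sum(log_rounds$alpha[log_rounds$model == m])
  }, numeric(1))
  apply_labels <- vapply(seq_len(M),
                         function(m) argmax_labels(model_probs(P_apply, m)),
                         integer(n_samples(P_apply)))
  apply_labels <- matrix(apply_labels, nrow = n_samples(P_apply))
  scores <- matrix(0, n_samples(P_apply), K)
  for (r in seq_len(nrow(log_rounds))) {
    m <- log_rounds$model[r]
    scores[cbind(seq_len(nrow(scores)), apply_labels[, m] + 1L)] <-
      scores[cbind(seq_len(nrow(scores)), apply_labels[, m] + 1L)] +
      log_rounds$alpha[r]
  }
  list(rounds = log_rounds, model_weights = model_weights,
       labels = max.col(scores, ties.method = "first") - 1L)
}

# concatenated per-model probability features for the meta-learner
stack_features <- function(P) {
  do.call(cbind, lapply(seq_len(n_models(P)), function(m) model_probs(P, m)))
}

# full-batch gradient descent on L2-penalized softmax cross-entropy,
# zero-initialized: deterministic, no RNG
fit_softmax <- function(X, y, K, iters, step, l2) {
  n <- nrow(X)
  W <- matrix(0, ncol(X), K)
  b <- rep(0, K)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  for (it in seq_len(iters)) {
    Z <- sweep(X %*% W, 2, b, "+")
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z)
    P <- P / rowSums(P)
    G <- (P - Y) / n
    W <- W - step * (t(X) %*% G + l2 * W)
    b <- b - step * colSums(G)
  }
  list(W = W, b = b)
}

predict_softmax <- function(fit, X) {
  Z <- sweep(X %*% fit$W, 2, fit$b, "+")
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z)
  P / rowSums(P)
}

#' Stacking with a linear softmax meta-learner
#'
#' Fits a multinomial linear map on the concatenated per-model class
#' probabilities of the validation set (full-batch gradient descent on
#' L2-penalized cross-entropy, zero initialization, fixed step and
#' iteration count — deterministic) and applies it to the test set.
#'
#' @param P_val,P_test Validation and test [prediction_set()]s.
#' @param y_val Validation labels.
#' @param iters Gradient-descent iterations (0 gives the zero-init model:
#'   uniform probabilities, so every label ties to class 0).
#' @param step Gradient step size.
#' @param l2 L2 penalty on the weight matrix.
#' @return List with `labels` (fused test labels), `probs`, and the
#'   meta-learner `fit`.
#' @export
stack_ensemble <- function(P_val, y_val, P_test, iters = 500L, step = 0.5,
                           l2 = 1e-4) {
  stopifnot(inherits(P_val, "prediction_set"),
            inherits(P_test, "prediction_set"))
  if (length(y_val) != n_samples(P_val)) {
    stop("y_val length must match P_val")
  }
  fit <- fit_softmax(stack_features(P_val), y_val, n_classes(P_val),
                     iters, step, l2)
  probs <- predict_softmax(fit, stack_features(P_test))
  list(labels = argmax_labels(probs), probs = probs, fit = fit)
}

#' Blending
#'
#' Identical to [stack_ensemble()], except the meta-learner is fit only on
#' a seeded held-out fraction of the validation set.
#'
#' @param P_val,P_test Validation and test [prediction_set()]s.
#' @param y_val Validation labels.
#' @param split_fraction Fraction of the validation set used for the
#'   meta-learner, in `(0, 1)`.
#' @param seed RNG seed for the split.
#' @param ... Passed on to [stack_ensemble()].
#' @return As [stack_ensemble()], plus the `holdout_idx` used.
#' @export
blend_ensemble <- function(P_val, y_val, P_test, split_fraction = 0.5,
                           seed = 1L, ...) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie strictly between 0 and 1")
  }
  n <- n_samples(P_val)
  K <- n_classes(P_val)
  set.seed(seed)
  idx <- sort(sample.int(n, floor(split_fraction * n)))
  if (length(idx) < K) {
    stop("blend split leaves fewer samples (", length(idx),
         ") than classes (", K, ")")
  }
  P_sub <- prediction_set(P_val$probs[, idx, , drop = FALSE],
                          P_val$model_ids, P_val$class_labels)
  out <- stack_ensemble(P_sub, y_val[idx], P_test, ...)
  out$holdout_idx <- idx
  out
}

#' Hybrid combiner
#'
#' Majority vote across the label outputs of several ensemble strategies;
#' ties break to the smallest class index.
#'
#' @param label_list List of equal-length 0-based label vectors.
#' @return Fused label vector.
#' @export
hybrid_vote <- function(label_list) {
  if (length(label_list) < 1) stop("need at least one label vector")
  lens <- lengths(label_list)
  if (length(unique(lens)) != 1L) stop("label vectors must share one length")
  votes <- do.call(cbind, label_list)
  K <- max(votes) + 1L
  apply(votes, 1, function(v) {
    which.max(tabulate(v + 1L, nbins = K)) - 1L
  })
}
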