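# Progressive image-resizing orchestration: a validated multi-stage plan
# (strictly increasing image sizes, non-increasing batch sizes,
# non-decreasing unfreeze fractions), an abstract trainer contract, a
# bundled deterministic reference trainer (pooled-pixel softmax
# classifier), and the stage-chaining runner that threads weights from one
# stage into the next and captures per-stage predictions for the ensemble
# module.

#' One training stage
#'
#' @param image_size Stage resolution in pixels.
#' @param batch_size Batch size, `>= 1`.
#' @param unfreeze_fraction Fraction of trainable backbone parameters
#'   (counted from the output end) unfrozen at this stage, in `[0, 1]`.
#' @param epochs Training epochs, `>= 1`.
#' @param stage_lr Stage learning rate (from [adjust_lr()]).
#' @return An object of class `stage_plan`.
#' @export
stage_plan <- function(image_size, batch_size, unfreeze_fraction, epochs,
                       stage_lr) {
  stopifnot(image_size >= 1, batch_size >= 1, epochs >= 1, stage_lr > 0,
            unfreeze_fraction >= 0, unfreeze_fraction <= 1)
  structure(list(image_size = as.integer(image_size),
                 batch_size = as.integer(batch_size),
                 unfreeze_fraction = unfreeze_fraction,
                 epochs = as.integer(epochs), stage_lr = stage_lr),
            class = "stage_plan")
}

#' Multi-stage progressive plan
#'
#' @param stages Ordered list of [stage_plan()]s.
#' @param base_alpha Base learning rate the stage rates were derived from.
#' @return An object of class `progressive_plan`.
#' @export
progressive_plan <- function(stages, base_alpha) {
  stopifnot(length(stages) >= 1, base_alpha > 0)
  structure(list(stages = stages, base_alpha = base_alpha),
            class = "progressive_plan")
}

#' @export
print.progressive_plan <- function(x, ...) {
  cat("<progressive_plan>", length(x$stages), "stages, base alpha",
      format(x$base_alpha), "\n")
  for (s in x$stages) {
    cat(sprintf("  %4dpx | batch %3d | unfreeze %.2f | %d epochs | lr %.4e\n",
                s$image_size, s$batch_size, s$unfreeze_fraction, s$epochs,
                s$stage_lr))
  }
  invisible(x)
}

#' Default five-stage plan
#'
#' Stages at 100, 128, 244, 256 and 299 px with batch sizes 64, 64, 32,
#' 32, 16 and unfreeze fractions 0, 0.25, 0.5, 0.75, 1. The per-size batch
#' sizes and unfreeze fractions are package defaults (chosen to shrink
#' batches and unfreeze more parameters as resolution grows) and fully
#' configurable; stage learning rates come from [adjust_lr()].
#'
#' @param base_alpha Base learning rate.
#' @param sizes Stage image sizes (strictly increasing).
#' @param batch_sizes Per-stage batch sizes (non-increasing).
#' @param unfreeze Per-stage unfreeze fractions (non-decreasing).
#' @param epochs Epochs per stage (scalar or per-stage vector).
#' @param cfg Scheduler configuration for the stage learning rates.
#' @return A [progressive_plan()].
#' @export
default_plan <- function(base_alpha = 0.001,
                         sizes = c(100L, 128L, 244L, 256L, 299L),
                         batch_sizes = c(64L, 64L, 32L, 32L, 16L),
                         unfreeze = c(0, 0.25, 0.5, 0.75, 1),
                         epochs = 8L,
                         cfg = scheduler_config()) {
  epochs <- rep_len(epochs, length(sizes))
  stages <- lapply(seq_along(sizes), function(k) {
    stage_plan(sizes[k], batch_sizes[k], unfreeze[k], epochs[k],
               adjust_lr(base_alpha, sizes[k], cfg))
  })
  progressive_plan(stages, base_alpha)
}

#' Validate a progressive plan
#'
#' Checks the monotonicity invariants: image sizes strictly increasing,
#' batch sizes non-increasing, unfreeze fractions non-decreasing. Never
#' throws.
#'
#' @param plan A [progressive_plan()].
#' @return Character vector of violations; empty iff the plan is valid.
#' @export
validate_plan <- function(plan) {
  sizes <- vapply(plan$stages, `[[`, numeric(1), "image_size")
  batches <- vapply(plan$stages, `[[`, numeric(1), "batch_size")
  unfreeze <- vapply(plan$stages, `[[`, numeric(1), "unfreeze_fraction")
  out <- character(0)
  if (any(diff(sizes) <= 0)) out <- c(out, "sizes not strictly increasing")
  if (any(diff(batches) > 0)) out <- c(out, "batch sizes not non-increasing")
  if (any(diff(unfreeze) < 0)) {
    out <- c(out, "unfreeze fractions not non-decreasing")
  }
  out
}

# block mean-pooling of an S x S image onto a g x g grid
pool_image <- function(img, g) {
  S <- nrow(img)
  cuts <- ceiling(seq_len(S) / (S / g))
  rowsum_r <- rowsum(img, cuts)
  pooled <- t(rowsum(t(rowsum_r), cuts))
  counts <- table(cuts)
  pooled / outer(as.numeric(counts), as.numeric(counts))
}

pool_features <- function(arr, idx, g) {
  t(vapply(idx, function(i) as.numeric(pool_image(arr[i, , ], g)),
           numeric(g * g)))
}

weights_fingerprint <- function(w) {
  v <- c(as.numeric(w$W), as.numeric(w$b))
  sprintf("w-%.12e-%.12e", sum(v * seq_along(v)), sum(v^2))
}

#' Bundled reference trainer
#'
#' A deliberately small, deterministic trainer satisfying the trainer
#' contract: every input image is mean-pooled onto a fixed `grid x grid`
#' feature map (so weights keep one shape across resolutions and can be
#' chained between stages), features are centered by a fixed offset, and a
#' linear softmax head is fit by full-batch gradient descent. The stage's
#' `unfreeze_fraction` selects the trailing fraction of feature weights
#' that are trainable (the bias always is); the gradient step size is
#' `stage_lr * step_scale`, so later, larger-resolution stages also train
#' with larger steps, mirroring the scheduler's intent.
#'
#' The contract is three functions: `init(n_classes)` returning a weights
#' handle, `train(weights, stage, images, labels)` returning the updated
#' handle, and `predict(weights, images)` returning an
#' `n_samples x n_classes` probability matrix. Handles carry an `id`
#' fingerprint used by the provenance log.
#'
#' @param grid Pooled feature grid side (default 8).
#' @param steps_per_epoch Gradient steps per declared epoch.
#' @param step_scale Multiplier from stage learning rate to gradient step.
#' @param l2 L2 penalty on the weight matrix.
#' @param center Fixed offset subtracted from every pooled feature (the
#'   approximate mean intensity of the synthetic images).
#' @return List of contract functions, class `cw_trainer`.
#' @export
reference_trainer <- function(grid = 8L, steps_per_epoch = 75L,
                              step_scale = 2000, l2 = 1e-3, center = 0.2) {
  init <- function(n_classes) {
    w <- list(W = matrix(0, grid * grid, n_classes), b = rep(0, n_classes))
    w$id <- weights_fingerprint(w)
    w
  }
  train <- function(weights, stage, images, labels) {
    X <- pool_features(images, seq_len(dim(images)[1]), grid) - center
    K <- ncol(weights$W)
    n <- nrow(X)
    Y <- matrix(0, n, K)
    Y[cbind(seq_len(n), labels + 1L)] <- 1
    n_train <- ceiling(stage$unfreeze_fraction * nrow(weights$W))
    trainable <- if (n_train > 0) {
      seq.int(nrow(weights$W) - n_train + 1L, nrow(weights$W))
    } else integer(0)
    step <- stage$stage_lr * step_scale
    W <- weights$W
    b <- weights$b
    for (it in seq_len(stage$epochs * steps_per_epoch)) {
      Z <- sweep(X %*% W, 2, b, "+")
      Z <- Z - apply(Z, 1, max)
      P <- exp(Z)
      P <- P / rowSums(P)
      G <- (P - Y) / n
      if (length(trainable) > 0) {
        W[trainable, ] <- W[trainable, ] -
          step * (t(X[, trainable, drop = FALSE]) %*% G +
                    l2 * W[trainable, , drop = FALSE])
      }
      b <- b - step * colSums(G)
    }
    out <- list(W = W, b = b)
    out$id <- weights_fingerprint(out)
    out
  }
  predict <- function(weights, images) {
    X <- pool_features(images, seq_len(dim(images)[1]), grid) - center
    Z <- sweep(X %*% weights$W, 2, weights$b, "+")
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z)
    P / rowSums(P)
  }
  structure(list(init = init, train = train, predict = predict,
                 grid = grid),
            class = "cw_trainer")
}

#' Run the progressive-resizing workflow
#'
#' Trains the stages of `plan` in order: stage 1 starts from the trainer's
#' initial weights, every later stage loads the previous stage's output
#' weights. After each stage the validation and test probability matrices
#' and a metric report are captured; the provenance log records the input
#' and output weights fingerprints of every stage so the chaining is
#' verifiable. A trainer failure at stage `k` aborts with stages
#' `1..k-1` preserved.
#'
#' @param trainer A trainer satisfying the [reference_trainer()] contract.
#' @param plan A valid [progressive_plan()]; sizes must be available in
#'   `data$images`.
#' @param data Dataset as produced by [gen_images()] (per-size image
#'   arrays, labels, train/val/test indices).
#' @param seed Seed set before the run (the reference trainer itself is
#'   RNG-free; custom trainers may draw from the stream).
#' @return An object of class `progressive_result`: per-stage `weights`,
#'   `val_probs`, `test_probs`, `metrics`, plus a `provenance` data frame
#'   and, on failure, the `error` message.
#' @export
run_progressive <- function(trainer, plan, data, seed = 1L) {
  violations <- validate_plan(plan)
  if (length(violations) > 0) {
    stop("invalid plan:\n  - ", paste(violations, collapse = "\n  - "))
  }
  set.seed(seed)
  K <- max(data$labels) + 1L
  w <- trainer$init(K)
  stages <- list()
  provenance <- data.frame(stage = integer(0), image_size = integer(0),
                           init_weights = character(0),
                           output_weights = character(0),
                           stringsAsFactors = FALSE)
  err <- NULL
  for (k in seq_along(plan$stages)) {
    st <- plan$stages[[k]]
    arr <- data$images[[as.character(st$image_size)]]
    if (is.null(arr)) {
      err <- paste0("stage ", k, ": no images at size ", st$image_size)
      break
    }
    init_id <- w$id
    w_new <- tryCatch(
      trainer$train(w, st,
                    arr[data$train_idx, , , drop = FALSE],
                    data$labels[data$train_idx]),
      error = function(e) e)
    if (inherits(w_new, "error")) {
      err <- paste0("stage ", k, " failed: ", conditionMessage(w_new))
      break
    }
    w <- w_new
    val_probs <- trainer$predict(w, arr[data$val_idx, , , drop = FALSE])
    test_probs <- trainer$predict(w, arr[data$test_idx, , , drop = FALSE])
    y_val <- data$labels[data$val_idx]
    stages[[k]] <- list(
      plan = st, weights = w, val_probs = val_probs, test_probs = test_probs,
      metrics = metric_report(y_val, argmax_labels(val_probs),
                              probs = val_probs, K = K))
    provenance <- rbind(provenance,
                        data.frame(stage = k, image_size = st$image_size,
                                   init_weights = init_id,
                                   output_weights = w$id,
                                   stringsAsFactors = FALSE))
  }
  structure(list(stages = stages, provenance = provenance, error = err,
                 plan = plan, seed = seed),
            class = "progressive_result")
}

#' @export
print.progressive_result <- function(x, ...) {
  cat("<progressive_result>", length(x$stages), "of",
      length(x$plan$stages), "stages completed\n")
  for (k in seq_along(x$stages)) {
    cat(sprintf("  stage %d (%dpx): val accuracy %.2f%%\n", k,
                x$stages[[k]]$plan$image_size,
                x$stages[[k]]$metrics$accuracy))
  }
  if (!is.null(x$error)) cat("  aborted:", x$error, "\n")
  invisible(x)
}

#' Stage prediction sets for ensemble fusion
#'
#' Stacks the per-stage validation (or test) probability matrices of a
#' progressive run into a [prediction_set()].
#'
#' @param result A `progressive_result`.
#' @param which `"val"` or `"test"`.
#' @return A [prediction_set()] with one model per completed stage.
#' @export
stage_predictions <- function(result, which = c("val", "test")) {
  which <- match.arg(which)
  field <- paste0(which, "_probs")
  mats <- lapply(result$stages, `[[`, field)
  probs <- array(0, dim = c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (m in seq_along(mats)) probs[m, , ] <- mats[[m]]
  prediction_set(probs,
                 model_ids = paste0("stage_",
                                    vapply(result$stages,
                                           function(s) s$plan$image_size,
                                           integer(1))))
}
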