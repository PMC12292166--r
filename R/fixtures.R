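# Seeded synthetic generators: benchmark objectives for the optimizers, a
# surrogate fitness surface with a known optimum for hyperparameter
# recovery tests, correlated multi-model class-probability fixtures that
# stand in for the per-resolution stage models, and labelled grayscale
# blob images renderable at every scheduled resolution. All generators are
# pure functions of their configuration, seed included.

#' Sphere benchmark
#' @param x Numeric position vector.
#' @return `sum(x^2)`; global minimum 0 at the origin.
#' @export
sphere <- function(x) sum(x^2)

#' Rastrigin benchmark
#' @param x Numeric position vector.
#' @return `10 d + sum(x^2 - 10 cos(2 pi x))`; global minimum 0 at the
#'   origin.
#' @export
rastrigin <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))

#' Rosenbrock benchmark
#' @param x Numeric position vector, length >= 2.
#' @return The banana-valley sum; global minimum 0 at the all-ones point.
#' @export
rosenbrock <- function(x) {
  d <- length(x)
  sum(100 * (x[-1] - x[-d]^2)^2 + (1 - x[-d])^2)
}

#' Benchmark function descriptor
#'
#' @param name `"sphere"`, `"rastrigin"` or `"rosenbrock"`.
#' @param dimension Problem dimension.
#' @return List with `name`, `fn`, `dimension`, `bounds` (two-column
#'   matrix), `minimum_position`, `minimum_value`.
#' @export
benchmark_function <- function(name = c("sphere", "rastrigin", "rosenbrock"),
                               dimension = 2L) {
  name <- match.arg(name)
  switch(name,
    sphere = list(name = name, fn = sphere, dimension = dimension,
                  bounds = matrix(rep(c(-5.12, 5.12), each = dimension),
                                  ncol = 2),
                  minimum_position = rep(0, dimension), minimum_value = 0),
    rastrigin = list(name = name, fn = rastrigin, dimension = dimension,
                     bounds = matrix(rep(c(-5.12, 5.12), each = dimension),
                                     ncol = 2),
                     minimum_position = rep(0, dimension), minimum_value = 0),
    rosenbrock = list(name = name, fn = rosenbrock, dimension = dimension,
                      bounds = matrix(rep(c(-2.048, 2.048), each = dimension),
                                      ncol = 2),
                      minimum_position = rep(1, dimension), minimum_value = 0))
}

#' Surrogate hyperparameter fitness surface
#'
#' Cheap analytic stand-in for a training loss with a unique known optimum
#' at `target`:
#' `(log10 lr - log10 lr*)^2 + (dropout - dropout*)^2 +
#'  0.5 * [optimizer != opt*] + 0.5 * [activation != act*] +
#'  ((n - n*) / 768)^2`.
#'
#' @param space Search space the target lives in (used for validation).
#' @param target A `hyperparams` list; the surface's unique minimizer.
#' @return Objective function over `hyperparams`, zero at `target`,
#'   positive elsewhere.
#' @export
surrogate_objective <- function(space = default_space(),
                                target = decode_position(
                                  encode_hyperparams(
                                    list(learning_rate = 1e-3, dropout = 0.5,
                                         optimizer = "Nadam",
                                         activation = "Sigmoid",
                                         n_neurons = 1024L), space), space)) {
  # round-trip through the codec guarantees the target is in-space
  target <- decode_position(encode_hyperparams(target, space), space)
  function(hp) {
    (log10(hp$learning_rate) - log10(target$learning_rate))^2 +
      (hp$dropout - target$dropout)^2 +
      0.5 * (hp$optimizer != target$optimizer) +
      0.5 * (hp$activation != target$activation) +
      ((hp$n_neurons - target$n_neurons) / 768)^2
  }
}

#' Correlated multi-model prediction fixtures
#'
#' Emulates the class-probability outputs of several correlated
#' classifiers with stated accuracies. True labels are uniform over the
#' classes. Correctness is decided by thresholding a latent uniform
#' variable at the target accuracy; with probability `correlation` a model
#' reuses a shared per-sample latent (so errors co-occur across models),
#' otherwise it draws its own. Correct samples get a probability row
#' peaked on the true class, incorrect ones on a random wrong class.
#'
#' @param n_models,n_samples,n_classes Counts, all `>= 1`.
#' @param accuracies Per-model target accuracy in `(1/K, 1]`; recycled to
#'   `n_models`.
#' @param correlation Inter-model error correlation in `[0, 1)`.
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @return List with `predictions` (a [prediction_set()]) and `labels`.
#' @export
gen_predictions <- function(n_models = 5L, n_samples = 1000L, n_classes = 3L,
                            accuracies = 0.85, correlation = 0.3,
                            seed = 1L) {
  stopifnot(n_models >= 1, n_samples >= 1, n_classes >= 2)
  accuracies <- rep_len(accuracies, n_models)
  if (any(accuracies <= 1 / n_classes) || any(accuracies > 1)) {
    stop("per-model accuracy must lie in (1/K, 1]")
  }
  if (correlation < 0 || correlation >= 1) {
    stop("correlation must lie in [0, 1)")
  }
  set.seed(seed)
  K <- n_classes
  labels <- sample(0:(K - 1), n_samples, replace = TRUE)
  u_shared <- stats::runif(n_samples)
  probs <- array(0, dim = c(n_models, n_samples, K))
  for (m in seq_len(n_models)) {
    use_shared <- stats::runif(n_samples) < correlation
    u_own <- stats::runif(n_samples)
    u <- ifelse(use_shared, u_shared, u_own)
    correct <- u < accuracies[m]
    peak <- stats::runif(n_samples, 0.65, 0.95)
    for (i in seq_len(n_samples)) {
      top <- if (correct[i]) labels[i] else {
        wrong <- setdiff(0:(K - 1), labels[i])
        wrong[sample.int(length(wrong), 1)]
      }
      rest <- stats::runif(K - 1)
      rest <- rest / sum(rest) * (1 - peak[i])
      row <- numeric(K)
      row[setdiff(seq_len(K), top + 1L)] <- rest
      row[top + 1L] <- peak[i]
      probs[m, i, ] <- row
    }
  }
  list(predictions = prediction_set(probs), labels = labels)
}

# rotated-Gaussian blob intensity on a unit-square pixel grid
render_scene <- function(scene, size) {
  px <- (seq_len(size) - 0.5) / size
  gx <- matrix(px, size, size)
  gy <- matrix(px, size, size, byrow = TRUE)
  img <- matrix(0.1, size, size)
  for (b in scene) {
    dx <- gx - b$cx
    dy <- gy - b$cy
    xr <- cos(b$angle) * dx + sin(b$angle) * dy
    yr <- -sin(b$angle) * dx + cos(b$angle) * dy
    img <- img + b$intensity * exp(-(xr^2 / b$rx^2 + yr^2 / b$ry^2))
  }
  img
}

#' Labelled multi-resolution synthetic images
#'
#' Renders each class-`k` image as `k + 1` bright elliptical blobs at
#' seeded positions on a noisy dark background, with the same scene
#' rendered at every requested size so progressive training stages see
#' consistent content. Deterministic per seed.
#'
#' @param n_per_class Images per class, `>= 2`.
#' @param n_classes Number of classes.
#' @param sizes Pixel sizes to render, e.g. `c(100, 128, 244, 256, 299)`.
#' @param noise_sd Additive Gaussian pixel noise standard deviation.
#' @param seed RNG seed.
#' @param split Train/validation/test fractions (must sum to 1); the split
#'   is stratified by class.
#' @return List with `images` (named by size: `n x S x S` arrays in
#'   `[0, 1]`), `labels` (0-based), `train_idx`, `val_idx`, `test_idx`,
#'   and the generating config.
#' @export
gen_images <- function(n_per_class = 10L, n_classes = 3L,
                       sizes = c(32L, 64L), noise_sd = 0.05, seed = 1L,
                       split = c(0.6, 0.2, 0.2)) {
  stopifnot(n_per_class >= 2, n_classes >= 1, length(sizes) >= 1)
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  set.seed(seed)
  n <- n_per_class * n_classes
  labels <- rep(0:(n_classes - 1), each = n_per_class)
  scenes <- lapply(labels, function(k) {
    lapply(seq_len(k + 1), function(b) {
      list(cx = stats::runif(1, 0.15, 0.85), cy = stats::runif(1, 0.15, 0.85),
           rx = stats::runif(1, 0.08, 0.10), ry = stats::runif(1, 0.08, 0.10),
           angle = stats::runif(1, 0, pi),
           intensity = stats::runif(1, 0.85, 0.95))
    })
  })
  images <- list()
  for (S in sizes) { # fixed loop order keeps the noise stream deterministic
    arr <- array(0, dim = c(n, S, S))
    for (i in seq_len(n)) {
      img <- render_scene(scenes[[i]], S)
      img <- img + matrix(stats::rnorm(S * S, 0, noise_sd), S, S)
      arr[i, , ] <- pmin(pmax(img, 0), 1)
    }
    images[[as.character(S)]] <- arr
  }
  idx_by_class <- split(seq_len(n), labels)
  # one seeded shuffle per class, reused for all three parts (stratified)
  set.seed(seed + 1L)
  perms <- lapply(idx_by_class, sample)
  take <- function(part) {
    unlist(lapply(perms, function(ix) {
      n_tr <- round(split[1] * length(ix))
      n_va <- round(split[2] * length(ix))
      switch(part,
             train = ix[seq_len(n_tr)],
             val = ix[n_tr + seq_len(n_va)],
             test = ix[-seq_len(n_tr + n_va)])
    }), use.names = FALSE)
  }
  list(images = images, labels = labels,
       train_idx = sort(take("train")), val_idx = sort(take("val")),
       test_idx = sort(take("test")),
       config = list(n_per_class = n_per_class, n_classes = n_classes,
                     sizes = sizes, noise_sd = noise_sd, seed = seed,
                     generator = "elliptical Gaussian blobs, count = class + 1,
additive Gaussian pixel noise"))
}

#' Write an image matrix as a PNG file
#'
#' @param img Matrix with values in `[0, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
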