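# Codec between the optimizer's real-valued positions and the mixed
# five-dimensional hyperparameter space (learning rate, dropout, optimizer,
# activation, first-dense-layer neurons), plus the tuning driver.

#' Describe one search dimension
#'
#' @param name Dimension label.
#' @param kind One of `"continuous"`, `"log_continuous"`, `"integer"`,
#'   `"categorical"`.
#' @param low,high Bounds for the numeric kinds (`low < high`). For
#'   `log_continuous` these are on the natural scale; the search coordinate
#'   is `log10` of the value.
#' @param categories Ordered label vector (categorical only, `>= 2` labels).
#' @return An object of class `dimension_spec`.
#' @export
dimension_spec <- function(name, kind, low = NULL, high = NULL,
                           categories = NULL) {
  kind <- match.arg(kind,
                    c("continuous", "log_continuous", "integer", "categorical"))
  if (kind == "categorical") {
    if (length(categories) < 2) stop("categorical dimensions need >= 2 categories")
  } else {
    if (is.null(low) || is.null(high) || low >= high) {
      stop("numeric dimensions need low < high")
    }
    if (kind == "log_continuous" && low <= 0) {
      stop("log_continuous dimensions need positive bounds")
    }
  }
  structure(list(name = name, kind = kind, low = low, high = high,
                 categories = categories),
            class = "dimension_spec")
}

#' The default five-dimensional hyperparameter space
#'
#' Learning rate log-continuous over `[1e-4, 1e-2]`; dropout continuous over
#' `[0.2, 0.5]`; optimizer categorical over Adam, RMSprop, AdamW, Adamax,
#' Nadam; activation categorical over ReLU, Tanh, Sigmoid; first-layer
#' neurons integer over `[256, 1024]` (a lower bound of 254 is accepted via
#' `neuron_low`).
#'
#' @param neuron_low Lower bound for the neuron count (default 256).
#' @return List of five [dimension_spec()] objects.
#' @export
default_space <- function(neuron_low = 256L) {
  list(
    dimension_spec("learning_rate", "log_continuous", low = 1e-4, high = 1e-2),
    dimension_spec("dropout", "continuous", low = 0.2, high = 0.5),
    dimension_spec("optimizer", "categorical",
                   categories = c("Adam", "RMSprop", "AdamW", "Adamax", "Nadam")),
    dimension_spec("activation", "categorical",
                   categories = c("ReLU", "Tanh", "Sigmoid")),
    dimension_spec("n_neurons", "integer", low = neuron_low, high = 1024L)
  )
}

#' Position-coordinate bounds of a search space
#'
#' Log-continuous dimensions search on the `log10` scale; categorical
#' dimensions use the embedding interval `[0, K)` (`K` = number of
#' categories).
#'
#' @param space List of [dimension_spec()] objects.
#' @return Two-column bounds matrix usable in [woa_config()].
#' @export
space_bounds <- function(space) {
  t(vapply(space, function(dim) {
    switch(dim$kind,
           log_continuous = c(log10(dim$low), log10(dim$high)),
           categorical = c(0, length(dim$categories)),
           c(dim$low, dim$high))
  }, numeric(2)))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Decode a real position into hyperparameters
#'
#' Total function: every real position yields an in-space value.
#' Log-continuous coordinates are clipped on the `log10` scale then
#' exponentiated; continuous coordinates clipped; integers rounded to
#' nearest (ties away from zero) then clipped; categorical coordinates
#' mapped through `floor` and clipped to the label range (the upper bound
#' `K` decodes to the last category).
#'
#' @param position Numeric vector, one coordinate per dimension.
#' @param space List of [dimension_spec()] objects.
#' @return Named list of decoded values, class `hyperparams`.
#' @examples
#' decode_position(c(-3, 0.5, 4.2, 2.2, 1024), default_space())
#' @export
decode_position <- function(position, space) {
  if (length(position) != length(space)) {
    stop("position length ", length(position), " does not match space (",
         length(space), " dimensions)")
  }
  vals <- lapply(seq_along(space), function(i) {
    dim <- space[[i]]
    x <- position[i]
    switch(dim$kind,
      continuous = min(max(x, dim$low), dim$high),
      log_continuous = 10^min(max(x, log10(dim$low)), log10(dim$high)),
      integer = as.integer(min(max(round_half_away(x), dim$low), dim$high)),
      categorical = {
        k <- min(max(floor(x), 0), length(dim$categories) - 1)
        dim$categories[k + 1]
      })
  })
  names(vals) <- vapply(space, `[[`, character(1), "name")
  structure(vals, class = "hyperparams")
}

#' @export
print.hyperparams <- function(x, ...) {
  cat("<hyperparams>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Encode hyperparameters into a real position
#'
#' Inverse of [decode_position()] up to the categorical cell: category index
#' `k` (0-based) maps to the cell midpoint `k + 0.5`, log-continuous values
#' to their `log10`.
#'
#' @param hp Named list (or `hyperparams`) of values valid for `space`.
#' @param space List of [dimension_spec()] objects.
#' @return Numeric position vector.
#' @export
encode_hyperparams <- function(hp, space) {
  vapply(space, function(dim) {
    v <- hp[[dim$name]]
    if (is.null(v)) stop("hyperparameter '", dim$name, "' missing")
    switch(dim$kind,
      continuous = as.numeric(v),
      log_continuous = log10(as.numeric(v)),
      integer = as.numeric(v),
      categorical = {
        k <- match(v, dim$categories)
        if (is.na(k)) {
          stop("unknown category '", v, "' for dimension '", dim$name, "'")
        }
        (k - 1) + 0.5
      })
  }, numeric(1))
}

#' Tune hyperparameters with a whale optimizer
#'
#' Wraps [decode_position()] inside the objective and runs the configured
#' optimizer (DCWOA by default, population 10, 20 iterations) over the
#' space's coordinate bounds.
#'
#' @param objective Function taking a `hyperparams` list, returning a scalar
#'   loss to minimize.
#' @param space List of [dimension_spec()] objects.
#' @param config Optional [woa_config()]; when `NULL` a DCWOA default is
#'   built (its `dimension`/`bounds` must match the space when supplied).
#' @param seed Seed used when `config` is `NULL`.
#' @return List with `best_hyperparams`, `best_fitness`, `trace`,
#'   `switch_events` and the underlying `result`.
#' @export
tune_hyperparams <- function(objective, space = default_space(),
                             config = NULL, seed = NULL) {
  bounds <- space_bounds(space)
  if (is.null(config)) {
    config <- woa_config("dcwoa", dimension = length(space), bounds = bounds,
                         population_size = 10L, max_iters = 20L, seed = seed)
  } else if (config$dimension != length(space)) {
    stop("config dimension does not match the search space")
  }
  res <- woa_run(function(pos) objective(decode_position(pos, space)), config)
  list(best_hyperparams = decode_position(res$best_position, space),
       best_fitness = res$best_fitness,
       trace = res$trace,
       switch_events = res$switch_events,
       result = res)
}
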