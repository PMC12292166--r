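# Chaotic sequence generators driving the coefficient randomness of the
# chaotic whale optimizers. Two maps are built in (logistic, sine); further
# maps can be attached through the registry hook.

.map_registry <- new.env(parent = emptyenv())

#' Specify a chaotic map
#'
#' Bundles a registered map identifier with its control parameter. The
#' logistic map uses `r` (full chaos at `r = 4`); the sine map has no free
#' parameter.
#'
#' @param map_id Name of a registered map, `"logistic"` or `"sine"` by
#'   default.
#' @param r Logistic control parameter, `0 < r <= 4`. Ignored by the sine map.
#' @return An object of class `chaotic_map_spec`.
#' @examples
#' spec <- chaotic_map_spec("logistic", r = 4)
#' chaotic_sequence(0.2, spec, 2)
#' @export
chaotic_map_spec <- function(map_id = "logistic", r = 4.0) {
  map_id <- match.arg(map_id, list_chaotic_maps())
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("`r` must be a single positive number, got ", deparse(r))
  }
  structure(list(map_id = map_id, r = r), class = "chaotic_map_spec")
}

#' @export
print.chaotic_map_spec <- function(x, ...) {
  cat("<chaotic_map_spec> map:", x$map_id,
      if (x$map_id == "logistic") paste0("(r = ", format(x$r), ")"), "\n")
  invisible(x)
}

#' One step of the logistic map
#'
#' Computes `r * x * (1 - x)`. For `r <= 4` the unit interval maps into
#' itself; `r = 4` gives fully chaotic dynamics.
#'
#' @param x Current value in `[0, 1]`.
#' @param r Control parameter in `(0, 4]`.
#' @return The next value, in `[0, 1]`.
#' @export
logistic_step <- function(x, r = 4.0) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("logistic map requires x in [0, 1], got ", deparse(x))
  }
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 4) {
    stop("logistic map requires r in (0, 4], got ", deparse(r))
  }
  r * x * (1 - x)
}

#' One step of the sine map
#'
#' Computes `sin(pi * x)`, mapping the unit interval into itself.
#'
#' @param x Current value in `[0, 1]`.
#' @return The next value, in `[0, 1]`.
#' @export
sine_step <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("sine map requires x in [0, 1], got ", deparse(x))
  }
  sin(pi * x)
}

#' Register a chaotic map
#'
#' Extension hook: adds a map to the registry so it can be named in a
#' [chaotic_map_spec()]. The step function receives `(x, spec)` and must
#' return a value in `[0, 1]`.
#'
#' @param name Map identifier.
#' @param step Function of `(x, spec)` returning the next value.
#' @param degenerate_seeds Seeds rejected by [chaotic_sequence()] because
#'   they collapse the sequence (fixed or eventually-fixed points).
#' @return `name`, invisibly.
#' @export
register_chaotic_map <- function(name, step, degenerate_seeds = c(0, 1)) {
  stopifnot(is.character(name), length(name) == 1L, is.function(step))
  assign(name, list(step = step, degenerate_seeds = degenerate_seeds),
         envir = .map_registry)
  invisible(name)
}

#' List registered chaotic maps
#' @return Character vector of map identifiers.
#' @export
list_chaotic_maps <- function() {
  sort(ls(.map_registry))
}

map_entry <- function(map_id) {
  if (!exists(map_id, envir = .map_registry, inherits = FALSE)) {
    stop("unknown chaotic map: ", map_id)
  }
  get(map_id, envir = .map_registry, inherits = FALSE)
}

chaotic_step <- function(x, spec) {
  map_entry(spec$map_id)$step(x, spec)
}

#' Screen a chaotic seed
#'
#' Rejects seeds that are fixed or eventually-fixed points of the chosen map
#' (for the logistic map at `r = 4`: 0, 0.25, 0.5, 0.75, 1; for the sine
#' map: 0, 1), since those collapse the sequence to a constant.
#'
#' @param x0 Candidate seed.
#' @param map_id Registered map identifier.
#' @return `TRUE` if admissible, `FALSE` otherwise.
#' @export
is_admissible_seed <- function(x0, map_id = "logistic") {
  entry <- map_entry(map_id)
  is.numeric(x0) && length(x0) == 1L && is.finite(x0) &&
    x0 > 0 && x0 < 1 &&
    !any(abs(x0 - entry$degenerate_seeds) < 1e-12)
}

#' Draw an admissible chaotic seed from the current RNG
#'
#' Uniform on `(0.01, 0.99)`, resampled in the (measure-zero) event that a
#' degenerate seed is hit.
#'
#' @param map_id Registered map identifier.
#' @return A seed value usable with [chaotic_sequence()].
#' @export
draw_chaotic_seed <- function(map_id = "logistic") {
  repeat {
    x0 <- stats::runif(1, 0.01, 0.99)
    if (is_admissible_seed(x0, map_id)) return(x0)
  }
}

#' Iterate a chaotic map
#'
#' Returns the first `n` iterates of the map applied to `x0` (element `k` is
#' the `k`-fold application; `x0` itself is not included). Deterministic
#' given `(x0, spec, n)`.
#'
#' @param x0 Seed in `(0, 1)`; degenerate seeds of the chosen map are
#'   rejected.
#' @param spec A [chaotic_map_spec()].
#' @param n Number of iterates, `n >= 1`.
#' @return Numeric vector of length `n`, each element in `[0, 1]`.
#' @examples
#' chaotic_sequence(0.2, chaotic_map_spec("logistic"), 2) # 0.64, 0.9216
#' @export
chaotic_sequence <- function(x0, spec, n) {
  stopifnot(inherits(spec, "chaotic_map_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count")
  }
  if (!is_admissible_seed(x0, spec$map_id)) {
    stop("inadmissible chaotic seed ", deparse(x0), " for map '", spec$map_id,
         "'; resample, e.g. with draw_chaotic_seed()")
  }
  out <- numeric(n)
  x <- x0
  for (k in seq_len(n)) {
    x <- chaotic_step(x, spec)
    out[k] <- x
  }
  out
}

# built-in maps
register_chaotic_map(
  "logistic",
  function(x, spec) logistic_step(x, spec$r),
  degenerate_seeds = c(0, 0.25, 0.5, 0.75, 1)
)
register_chaotic_map(
  "sine",
  function(x, spec) sine_step(x),
  degenerate_seeds = c(0, 1)
)
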