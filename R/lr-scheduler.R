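# Image-size-adaptive learning-rate rule: the stage learning rate is the
# base rate scaled by beta(S)^(S / S0) and clamped to [0.1 * alpha,
# 10 * alpha]. Larger scheduled sizes get larger rates.

#' Scheduler configuration
#'
#' @param base_size Reference image size `S0` in pixels (default 100, the
#'   smallest scheduled size, so the first stage trains at the base rate).
#' @param beta_table Named numeric vector mapping image size to the scaling
#'   coefficient beta; sizes not in the table fall back to 1.
#' @param clamp_low_factor,clamp_high_factor Clamp interval for the adjusted
#'   rate as multiples of the base rate.
#' @return An object of class `scheduler_config`.
#' @export
scheduler_config <- function(base_size = 100L,
                             beta_table = c("100" = 1.0, "128" = 1.05,
                                            "244" = 1.1, "256" = 1.15,
                                            "299" = 1.2),
                             clamp_low_factor = 0.1,
                             clamp_high_factor = 10.0) {
  if (base_size < 1) stop("base_size must be a positive size in pixels")
  if (any(beta_table < 0)) stop("all beta values must be >= 0")
  if (!(clamp_low_factor < 1 && 1 < clamp_high_factor)) {
    stop("need clamp_low_factor < 1 < clamp_high_factor")
  }
  structure(list(base_size = as.integer(base_size), beta_table = beta_table,
                 clamp_low_factor = clamp_low_factor,
                 clamp_high_factor = clamp_high_factor),
            class = "scheduler_config")
}

#' Scaling coefficient beta for an image size
#'
#' Table lookup with a default of 1 for sizes outside the scheduled set
#' `{100: 1.0, 128: 1.05, 244: 1.1, 256: 1.15, 299: 1.2}`.
#'
#' @param S Image size(s) in pixels, `S >= 1`.
#' @param cfg A [scheduler_config()].
#' @return Numeric vector of beta values.
#' @export
scaling_factor <- function(S, cfg = scheduler_config()) {
  if (any(S < 1)) stop("image size must be >= 1")
  beta <- cfg$beta_table[as.character(S)]
  beta[is.na(beta)] <- 1.0
  unname(beta)
}

#' Adjust the learning rate for an image size
#'
#' `alpha' = alpha * beta(S)^(S / S0)`, clamped to
#' `[clamp_low_factor * alpha, clamp_high_factor * alpha]` (0.1x to 10x by
#' default) to prevent extreme excursions. Vectorized over `S`.
#'
#' @param alpha Base learning rate, `> 0`.
#' @param S Image size(s) in pixels.
#' @param cfg A [scheduler_config()].
#' @return Adjusted rate(s), always within the clamp interval.
#' @examples
#' adjust_lr(0.001, c(100, 128, 244, 256, 299))
#' @export
adjust_lr <- function(alpha, S, cfg = scheduler_config()) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("alpha must be a single positive learning rate, got ", deparse(alpha))
  }
  beta <- scaling_factor(S, cfg)
  raw <- alpha * beta^(S / cfg$base_size)
  pmax(pmin(raw, cfg$clamp_high_factor * alpha), cfg$clamp_low_factor * alpha)
}

#' Full schedule table
#'
#' @param alpha Base learning rate.
#' @param sizes Image sizes; defaults to the scheduled set in the beta
#'   table.
#' @param cfg A [scheduler_config()].
#' @return Data frame with columns `size`, `beta`, `lr`.
#' @export
lr_schedule_table <- function(alpha, sizes = NULL, cfg = scheduler_config()) {
  if (is.null(sizes)) sizes <- as.integer(names(cfg$beta_table))
  data.frame(size = sizes,
             beta = scaling_factor(sizes, cfg),
             lr = adjust_lr(alpha, sizes, cfg))
}
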