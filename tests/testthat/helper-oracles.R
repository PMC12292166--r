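# Independent oracles kept deliberately naive: a line-by-line transcription
# of the whale update loop with frozen draws, a pair-counting AUC, and a
# from-scratch minimal whale optimizer used to cross-check convergence.

# One whale iteration, transcribed literally from the published update
# rules: in-place agent updates, the leader held fixed for the loop, then
# clipping. `draws[[i]]` supplies the frozen randomness for agent i:
# r_s (branch scalar), p, l, r_v (per-dimension vector), j (random agent,
# used only by the exploration branch).
oracle_whale_iteration <- function(positions, leader, a, b, draws, bounds) {
  out <- positions
  for (i in seq_len(nrow(positions))) {
    d <- draws[[i]]
    A_scalar <- 2 * a * d$r_s - a
    A <- 2 * a * d$r_v - a
    C <- 2 * d$r_v
    X <- out[i, ]
    if (d$p < 0.5) {
      if (abs(A_scalar) < 1) {
        D <- abs(C * leader - X)
        newX <- leader - A * D
      } else {
        Xr <- out[d$j, ]
        D <- abs(C * Xr - X)
        newX <- Xr - A * D
      }
    } else {
      Dp <- abs(leader - X)
      newX <- Dp * exp(b * d$l) * cos(2 * pi * d$l) + leader
    }
    out[i, ] <- pmin(pmax(newX, bounds[, 1]), bounds[, 2])
  }
  out
}

# Stub sampler replaying the frozen draws in the order the step consumes
# them (r_scalar, p, l, r_vec per agent; rand_index only on exploration).
make_stub_sampler <- function(draws) {
  q <- new.env()
  q$r_s <- lapply(draws, `[[`, "r_s")
  q$p <- lapply(draws, `[[`, "p")
  q$l <- lapply(draws, `[[`, "l")
  q$r_v <- lapply(draws, `[[`, "r_v")
  q$j <- Filter(Negate(is.null), lapply(draws, `[[`, "j"))
  pop <- function(name) {
    v <- q[[name]][[1]]
    q[[name]] <- q[[name]][-1]
    v
  }
  list(
    r_scalar = function() pop("r_s"),
    r_vec = function(d) {
      v <- pop("r_v")
      stopifnot(length(v) == d)
      v
    },
    p = function() pop("p"),
    l = function() pop("l"),
    rand_index = function(n) pop("j")
  )
}

# AUC by brute force over all positive-negative pairs (ties count 1/2).
brute_force_auc <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Minimal independent whale optimizer (plain variant, scalar coefficients
# broadcast over dimensions) used only as a convergence cross-check.
naive_whale_optimizer <- function(objective, dim, bounds, pop, iters, seed) {
  set.seed(seed)
  lo <- bounds[1]
  hi <- bounds[2]
  X <- matrix(runif(pop * dim, lo, hi), pop)
  fit <- apply(X, 1, objective)
  best <- which.min(fit)
  leader <- X[best, ]
  leader_fit <- fit[best]
  for (t in 0:(iters - 1)) {
    a <- 2 - 2 * t / iters
    for (i in seq_len(pop)) {
      r1 <- runif(1)
      A <- 2 * a * r1 - a
      C <- 2 * runif(1)
      p <- runif(1)
      l <- runif(1, -1, 1)
      X[i, ] <- if (p >= 0.5) {
        abs(leader - X[i, ]) * exp(l) * cos(2 * pi * l) + leader
      } else if (abs(A) < 1) {
        leader - A * abs(C * leader - X[i, ])
      } else {
        Xr <- X[sample.int(pop, 1), ]
        Xr - A * abs(C * Xr - X[i, ])
      }
      X[i, ] <- pmin(pmax(X[i, ], lo), hi)
    }
    fit <- apply(X, 1, objective)
    if (min(fit) < leader_fit) {
      leader_fit <- min(fit)
      leader <- X[which.min(fit), ]
    }
  }
  leader_fit
}

# Exhaustive-grid minimizer of the surrogate fitness surface: 20 x 20
# continuous grid (log10 learning rate x dropout) x every categorical
# cell x a 20-point neuron grid.
grid_minimize_surrogate <- function(fn, space) {
  lr_grid <- seq(-4, -2, length.out = 20)
  dr_grid <- seq(0.2, 0.5, length.out = 20)
  nn_grid <- round(seq(256, 1024, length.out = 20))
  opts <- space[[3]]$categories
  acts <- space[[4]]$categories
  best <- NULL
  best_val <- Inf
  for (lr in lr_grid) for (dr in dr_grid) for (o in opts) for (a in acts) {
    for (nn in nn_grid) {
      hp <- structure(list(learning_rate = 10^lr, dropout = dr, optimizer = o,
                           activation = a, n_neurons = nn),
                      class = "hyperparams")
      v <- fn(hp)
      if (v < best_val) {
        best_val <- v
        best <- hp
      }
    }
  }
  list(hp = best, value = best_val)
}
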