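# Independent reference computations for the network dynamics.
#
# The energy evaluator below is written from the model definition with plain
# nested loops over grid coordinates (no reuse of the package's vectorized
# paths): inference performs gradient descent on
#   E_l(y_l) = 1/2 * (squared bottom-up errors made by area l)
#            + 1/2 * eta_l * (squared top-down errors received by area l)
#            + alpha_y_l * sum(|y_l|)
# and learning on the batch-mean of 1/2 * e_beta + alpha_w * ||W||_1, so the
# update rules should match -gamma * (finite-difference gradient).

# total squared prediction error of area pair (level-1, level), batch b
oracle_pair_sq_err <- function(net, state, level, b = 1) {
  cfg <- net$config
  up <- cfg$geometry[[level + 1]]
  lo <- cfg$geometry[[level]]
  low <- if (level == 1) state$y0 else state$y[[level - 1]]
  s <- up$rf_size
  n_low <- lo$population_size
  tot <- 0
  for (kr in seq_len(up$grid_rows)) for (kc in seq_len(up$grid_cols)) {
    k <- (kc - 1) * up$grid_rows + kr
    W <- matrix(net$weights[[level]][, , k], ncol = up$population_size)
    pred <- pmax(W %*% state$y[[level]][, b, k], 0)
    for (qc in 0:(s - 1)) for (qr in 0:(s - 1)) {
      q <- qc * s + qr + 1
      j <- (kc - 1 + qc) * lo$grid_rows + (kr + qr)
      rows <- ((q - 1) * n_low + 1):(q * n_low)
      tot <- tot + sum((low[, b, j] - pred[rows])^2)
    }
  }
  tot
}

# energy whose gradient in y_level drives the inference step (batch element b)
oracle_inference_energy <- function(net, state, level, b = 1) {
  cfg <- net$config
  e <- 0.5 * oracle_pair_sq_err(net, state, level, b)
  if (level < cfg$n_areas)
    e <- e + 0.5 * cfg$eta[level] * oracle_pair_sq_err(net, state, level + 1, b)
  e + cfg$alpha_y[level] * sum(abs(state$y[[level]][, b, ]))
}

# energy whose gradient in the pair-`level` weights drives the learning step
oracle_learning_energy <- function(net, state, level) {
  B <- state$batch_size
  e <- 0
  for (b in seq_len(B)) e <- e + 0.5 * oracle_pair_sq_err(net, state, level, b)
  e / B + net$config$alpha_w * sum(abs(net$weights[[level]]))
}

# central finite difference of f at x (scalar)
fd_central <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# a small two-pair test network: 3x3 input, rf 2, populations of 2 and 3
toy_network <- function(gamma_y = 0.05, gamma_w = 0.05,
                        alpha_y = 0.001, alpha_w = 0.001, eta = 1,
                        seed = 1) {
  cfg <- dhpc_config(input_size = c(3, 3, 1), population_sizes = c(2, 3),
                     rf_size = 2, gamma_y = gamma_y, gamma_w = gamma_w,
                     alpha_y = alpha_y, alpha_w = alpha_w, eta = eta,
                     n_inference_steps = 20, batch_size = 1)
  dhpc_network(cfg, seed = seed)
}

# draw a random state/weight configuration away from every kink: all
# activities well above 0, every prediction pre-activation away from 0
random_nondegenerate <- function(net, margin = 0.05, max_tries = 200) {
  cfg <- net$config
  for (try in seq_len(max_tries)) {
    for (l in seq_len(cfg$n_areas)) {
      w <- net$weights[[l]]
      net$weights[[l]][] <- stats::runif(length(w), -1, 1)
    }
    imgs <- array(stats::runif(prod(c(cfg$input_size, 1)), 0.3, 1.2),
                  dim = c(cfg$input_size, 1))
    state <- new_state(net, imgs)
    for (l in seq_len(cfg$n_areas))
      state$y[[l]][] <- stats::runif(length(state$y[[l]]), 0.3, 1.2)
    ok <- TRUE
    for (l in seq_len(cfg$n_areas)) {
      for (k in seq_len(dim(net$weights[[l]])[3])) {
        W <- matrix(net$weights[[l]][, , k],
                    ncol = cfg$geometry[[l + 1]]$population_size)
        pre <- W %*% state$y[[l]][, 1, k]
        if (any(abs(pre) < margin)) { ok <- FALSE; break }
      }
      if (!ok) break
      if (any(abs(net$weights[[l]]) < 1e-3)) { ok <- FALSE; break }
    }
    if (ok) return(list(net = net, state = state))
  }
  stop("could not draw a non-degenerate configuration")
}

# gradient check of one inference step; returns the max relative error
inference_grad_relerr <- function(net, state) {
  cfg <- net$config
  new <- inference_step(state, net)
  worst <- 0
  for (l in seq_len(cfg$n_areas)) {
    delta <- new$y[[l]] - state$y[[l]]
    grad <- array(0, dim = dim(state$y[[l]]))
    for (i in seq_along(grad)) {
      grad[i] <- fd_central(function(v) {
        s2 <- state
        s2$y[[l]][i] <- v
        oracle_inference_energy(net, s2, l)
      }, state$y[[l]][i])
    }
    expected <- -cfg$gamma_y * grad
    worst <- max(worst, max(abs(delta - expected)) /
                          max(abs(expected), 1e-8))
  }
  worst
}

# gradient check of one learning step; returns the max relative error
learning_grad_relerr <- function(net, state) {
  cfg <- net$config
  new <- learning_step(state, net)
  worst <- 0
  for (l in seq_len(cfg$n_areas)) {
    delta <- new$weights[[l]] - net$weights[[l]]
    grad <- array(0, dim = dim(net$weights[[l]]))
    for (i in seq_along(grad)) {
      grad[i] <- fd_central(function(v) {
        n2 <- net
        n2$weights[[l]][i] <- v
        oracle_learning_energy(n2, state, l)
      }, net$weights[[l]][i])
    }
    expected <- -cfg$gamma_w * grad
    worst <- max(worst, max(abs(delta - expected)) /
                          max(abs(expected), 1e-8))
  }
  worst
}
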