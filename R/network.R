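#' Create a DHPC network with freshly initialized weights
#'
#' Interareal weights are stored once per area pair and serve both the
#' feedback (prediction) and feedforward (error back-projection) direction.
#' For area pair \code{(l-1, l)} the weights form an array of dimension
#' \code{(s_l^2 * n_(l-1), n_l, P_l)}: slice \code{k} is the feedback weight
#' matrix of upper population \code{k}, with rows ordered lower-neuron-fastest
#' within each RF offset. There is no weight sharing across grid positions.
#'
#' Initial weights are drawn from a zero-mean uniform distribution with
#' half-width \code{1/sqrt(n_l)} (the fan-in of a predicted lower neuron),
#' which keeps initial predictions on the scale of the activities.
#'
#' @param config a \code{\link{dhpc_config}}.
#' @param seed integer seed for the weight draw (and recorded for provenance).
#' @return An object of class \code{"dhpc_network"}: list with \code{config},
#'   \code{weights} (list of 3-d arrays), \code{rf_index} (per-pair
#'   receptive-field index maps), \code{iteration} counter and \code{seed}.
#' @export
dhpc_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "dhpc_config"))
  set.seed(seed)
  weights <- vector("list", config$n_areas)
  rf_index <- vector("list", config$n_areas)
  for (l in seq_len(config$n_areas)) {
    up <- config$geometry[[l + 1]]
    lo <- config$geometry[[l]]
    M <- up$rf_size^2 * lo$population_size
    P <- up$grid_rows * up$grid_cols
    half <- 1 / sqrt(up$population_size)
    weights[[l]] <- array(stats::runif(M * up$population_size * P, -half, half),
                          dim = c(M, up$population_size, P))
    rf_index[[l]] <- rf_index_map(config, l)
  }
  structure(list(config = config, weights = weights, rf_index = rf_index,
                 iteration = 0L, seed = as.integer(seed)),
            class = "dhpc_network")
}

#' @export
print.dhpc_network <- function(x, ...) {
  cnt <- count_architecture(x$config)
  cat(sprintf("DHPC network: %d area(s), %d neurons, %s synapses, %d training iteration(s)\n",
              x$config$n_areas, sum(cnt$areas$neurons[-1]),
              format(sum(cnt$connections$synapses), big.mark = ","),
              x$iteration))
  invisible(x)
}

#' Rectified linear activation
#'
#' Elementwise \code{max(x, 0)}; the activation used for predictions so that
#' firing rates stay nonnegative.
#' @param x numeric vector/array.
#' @return same shape as \code{x}.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Prediction gate (ReLU derivative)
#'
#' Returns 1 where the prediction is strictly positive and 0 elsewhere.
#' Gating multiplies both the error back-projection during inference and the
#' Hebbian term during learning.
#' @param y_hat prediction values (nonnegative).
#' @return binary array of the same shape.
#' @export
gate <- function(y_hat) {
  (y_hat > 0) + 0
}

#' Top-down prediction of one population
#'
#' Computes \code{relu(W \%*\% y_upper)}: the prediction a higher-area
#' population sends to the lower-area populations in its receptive field.
#'
#' @param weights matrix \code{(s^2 * n_lower) x n_upper} (a weight slice for
#'   one population).
#' @param y_upper activity vector (length \code{n_upper}) or matrix
#'   \code{n_upper x B}.
#' @return predicted activity, RF-stacked (one block of \code{n_lower} rows
#'   per RF position); nonnegative.
#' @export
predict_down <- function(weights, y_upper) {
  weights <- as.matrix(weights)
  if (is.null(dim(y_upper))) y_upper <- matrix(y_upper, ncol = 1)
  if (ncol(weights) != nrow(y_upper))
    stop("weight slice and upper activity are not conformable")
  out <- relu(weights %*% y_upper)
  if (ncol(out) == 1) drop(out) else out
}

#' Bottom-up prediction error
#'
#' \code{beta = y_lower - y_hat}; computed in the lower area and transmitted
#' upward. May be negative.
#' @param y_lower actual lower-area activity.
#' @param y_hat top-down prediction of it.
#' @return error of the same shape.
#' @export
bottom_up_error <- function(y_lower, y_hat) {
  if (length(y_lower) != length(y_hat))
    stop("activity and prediction lengths differ")
  y_lower - y_hat
}

#' Initialize a network state for a batch of images
#'
#' Area 0 is clamped to the images; activities of areas 1..N are set to
#' \code{init_activity}.
#'
#' @param network a \code{\link{dhpc_network}}.
#' @param images array \code{H x W x C x B} (or \code{H x W x B} for a single
#'   channel) with values in \code{[0, 1]}.
#' @param init_activity initial activity; defaults to the config value.
#' @return An object of class \code{"dhpc_state"}: list with \code{y0} (the
#'   clamped input, \code{C x B x P0}) and \code{y}, a list of per-area
#'   activity arrays \code{n_l x B x P_l}.
#' @export
new_state <- function(network, images, init_activity = NULL) {
  cfg <- network$config
  if (is.null(init_activity)) init_activity <- cfg$init_activity
  y0 <- images_to_input(images, cfg)
  B <- dim(y0)[2]
  y <- lapply(seq_len(cfg$n_areas), function(l) {
    g <- cfg$geometry[[l + 1]]
    array(init_activity, dim = c(g$population_size, B,
                                 g$grid_rows * g$grid_cols))
  })
  structure(list(y0 = y0, y = y, batch_size = B), class = "dhpc_state")
}

# images (H x W x C x B) -> input cube (C x B x H*W), population index
# column-major over the pixel grid
images_to_input <- function(images, config) {
  d <- dim(images)
  H <- config$input_size[1]; W <- config$input_size[2]; C <- config$input_size[3]
  if (is.null(d) || length(d) == 2) stop("images must be an array")
  if (length(d) == 3) {
    if (C != 1 || d[1] != H || d[2] != W)
      stop("image dimensions do not match the network input size")
    images <- array(images, dim = c(H, W, 1, d[3]))
    d <- dim(images)
  }
  if (!all(d[1:3] == c(H, W, C)))
    stop("image dimensions do not match the network input size")
  y0 <- aperm(images, c(3, 4, 1, 2))
  dim(y0) <- c(C, d[4], H * W)
  y0
}

# inverse of images_to_input
input_to_images <- function(y0, config) {
  H <- config$input_size[1]; W <- config$input_size[2]; C <- config$input_size[3]
  B <- dim(y0)[2]
  dim(y0) <- c(C, B, H, W)
  aperm(y0, c(3, 4, 1, 2))
}

#' Run inference steps on a clamped input
#'
#' Performs synchronous gradient-style updates of all activities at fixed
#' weights. Each step evaluates, from the pre-step state, every top-down
#' prediction, its bottom-up error and its gated back-projection, then updates
#' every area at once:
#' \code{Delta y = -gamma_y * (eta * sum(top-down errors) -
#' sum(g(yhat) o beta)' W + alpha_y)}, followed by rectification. The top area
#' receives no top-down term; boundary populations sum only over their
#' existing predictors.
#'
#' @param state a \code{\link{new_state}} (or the state returned by a previous
#'   call).
#' @param network the network.
#' @param n_steps number of inference steps; defaults to the configured
#'   \code{n_inference_steps}.
#' @param record_energy if \code{TRUE} the result carries an
#'   \code{(n_steps + 1) x N} matrix \code{energy} of per-area total squared
#'   bottom-up error (first row: before the first step; last row: at the
#'   returned state).
#' @return the updated \code{dhpc_state}, with attribute \code{energy} when
#'   recorded.
#' @export
settle <- function(state, network, n_steps = NULL, record_energy = FALSE) {
  cfg <- network$config
  if (is.null(n_steps)) n_steps <- cfg$n_inference_steps
  res <- settle_cpp(state$y0, network$weights, network$rf_index, state$y,
                    cfg$eta, cfg$alpha_y, cfg$gamma_y, as.integer(n_steps),
                    record_energy)
  state$y <- res$y
  if (record_energy) attr(state, "energy") <- res$energy
  state
}

#' Single synchronous inference step
#'
#' Convenience wrapper around \code{\link{settle}} with \code{n_steps = 1}.
#' @inheritParams settle
#' @return the updated state.
#' @export
inference_step <- function(state, network) {
  settle(state, network, n_steps = 1L)
}

#' Gated Hebbian learning step
#'
#' Updates every interareal weight from a settled state:
#' \code{Delta W = -gamma_w * (-g(yhat) o beta y' + alpha_w * sign(W))},
#' with the gate applied along the lower-neuron dimension of the outer
#' product, the Hebbian term averaged over the batch, and \code{sign(0) = 0}
#' so exactly-zero weights do not decay. Intra-areal connections do not exist
#' in the model and are never modified.
#'
#' @param state a settled \code{dhpc_state}.
#' @param network the network.
#' @return the network with updated weights and incremented iteration counter.
#' @export
learning_step <- function(state, network) {
  cfg <- network$config
  deltas <- learn_cpp(state$y0, network$weights, network$rf_index, state$y,
                      cfg$gamma_w, cfg$alpha_w)
  for (l in seq_along(network$weights))
    network$weights[[l]] <- network$weights[[l]] + deltas[[l]]
  network$iteration <- network$iteration + 1L
  network
}

#' Per-population prediction-error energies of one area
#'
#' \code{e_beta}: for each population of the area, the sum over its RF
#' positions of squared bottom-up errors. \code{e_tau}: the eta-weighted sum
#' of squared top-down errors the population receives from its existing
#' higher-area predictors (absent for the top area).
#'
#' @param state a \code{dhpc_state}.
#' @param network the network.
#' @param level area index in \code{1..N}.
#' @return list with numeric vectors \code{e_beta} and \code{e_tau} (length =
#'   populations of the area; \code{e_tau} is all zero for the top area).
#' @export
area_energy <- function(state, network, level) {
  cfg <- network$config
  stopifnot(level >= 1, level <= cfg$n_areas)
  err <- pair_errors(state, network, level)
  e_beta <- apply(err$beta, 3, function(m) sum(m^2))
  P <- n_populations(cfg, level)
  e_tau <- numeric(P)
  if (level < cfg$n_areas) {
    above <- pair_errors(state, network, level + 1L)
    idx <- network$rf_index[[level + 1L]]
    n_low <- cfg$geometry[[level + 1L]]$population_size
    for (k in seq_len(ncol(idx))) {
      for (q in seq_len(nrow(idx))) {
        rows <- ((q - 1) * n_low + 1):(q * n_low)
        j <- idx[q, k]
        e_tau[j] <- e_tau[j] + sum(above$beta[rows, , k]^2)
      }
    }
    e_tau <- cfg$eta[level] * e_tau
  }
  list(e_beta = e_beta, e_tau = e_tau)
}

# predictions/errors of area pair (level-1, level) computed in R; used by
# area_energy, decoding and the analysis of trained weights.
pair_errors <- function(state, network, level) {
  cfg <- network$config
  low <- if (level == 1) state$y0 else state$y[[level - 1]]
  yl <- state$y[[level]]
  W <- network$weights[[level]]
  idx <- network$rf_index[[level]]
  n_low <- dim(low)[1]; B <- dim(low)[2]
  M <- dim(W)[1]; P <- dim(W)[3]
  yhat <- array(0, dim = c(M, B, P))
  beta <- array(0, dim = c(M, B, P))
  for (k in seq_len(P)) {
    ylow <- matrix(0, M, B)
    for (q in seq_len(nrow(idx)))
      ylow[((q - 1) * n_low + 1):(q * n_low), ] <- low[, , idx[q, k]]
    pred <- relu(matrix(W[, , k], M) %*% matrix(yl[, , k], ncol = B))
    yhat[, , k] <- pred
    beta[, , k] <- ylow - pred
  }
  list(yhat = yhat, beta = beta)
}

#' Reconstruct the input image from the latent representation of an area
#'
#' Cascades the generative (feedback) mapping downward from area \code{m} to
#' area 0. In the receptive-field variant the overlapping predictions arriving
#' at each lower population are averaged; in the fully connected variant every
#' lower population receives exactly one prediction and the decode is the
#' plain generative cascade.
#'
#' @param network the network.
#' @param latent either a \code{dhpc_state} (its area-\code{m} activity is
#'   used) or an activity array \code{n_m x B x P_m}.
#' @param area the area \code{m} in \code{1..N} to decode from.
#' @return reconstructed images, array \code{H x W x C x B}; values >= 0.
#' @export
decode_from_area <- function(network, latent, area) {
  cfg <- network$config
  stopifnot(area >= 1, area <= cfg$n_areas)
  y <- if (inherits(latent, "dhpc_state")) latent$y[[area]] else latent
  g <- cfg$geometry[[area + 1]]
  if (!all(dim(y)[c(1, 3)] == c(g$population_size, g$grid_rows * g$grid_cols)))
    stop("latent activity does not match the geometry of the requested area")
  B <- dim(y)[2]
  for (l in area:1) {
    lo <- cfg$geometry[[l]]
    W <- network$weights[[l]]
    idx <- network$rf_index[[l]]
    n_low <- lo$population_size
    P_low <- lo$grid_rows * lo$grid_cols
    acc <- array(0, dim = c(n_low, B, P_low))
    cnt <- integer(P_low)
    for (k in seq_len(dim(W)[3])) {
      pred <- relu(matrix(W[, , k], dim(W)[1]) %*% matrix(y[, , k], ncol = B))
      for (q in seq_len(nrow(idx))) {
        j <- idx[q, k]
        acc[, , j] <- acc[, , j] + pred[((q - 1) * n_low + 1):(q * n_low), ,
                                        drop = FALSE]
        cnt[j] <- cnt[j] + 1L
      }
    }
    for (j in seq_len(P_low)) acc[, , j] <- acc[, , j] / cnt[j]
    y <- acc
  }
  input_to_images(y, cfg)
}

#' Save / load a network checkpoint
#'
#' Checkpoints carry the full network (config, weights, iteration counter and
#' seed) in R's native serialization.
#' @param network a \code{dhpc_network}.
#' @param path file path.
#' @return \code{save_checkpoint} returns the path invisibly;
#'   \code{load_checkpoint} returns the network.
#' @export
save_checkpoint <- function(network, path) {
  stopifnot(inherits(network, "dhpc_network"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  network <- readRDS(path)
  if (!inherits(network, "dhpc_network")) stop("not a dhpc checkpoint: ", path)
  network
}
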