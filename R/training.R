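#' Train a DHPC network
#'
#' Runs the training protocol: per iteration a batch is drawn (sampling
#' without replacement within an epoch, reshuffled every epoch), activities
#' are reset to \code{init_activity}, \code{n_inference_steps} inference steps
#' settle the state, and one gated Hebbian learning step updates the weights.
#' The per-area mean squared bottom-up error of the settled state is logged
#' for every iteration.
#'
#' @param network a \code{\link{dhpc_network}}.
#' @param images array \code{H x W x C x n} (or \code{H x W x n}) of training
#'   images in \code{[0, 1]}.
#' @param n_iterations number of batch presentations (each with one learning
#'   step).
#' @param batch_size stimuli per batch; defaults to the configured value,
#'   capped at the dataset size.
#' @param seed optional seed for batch sampling; \code{NULL} leaves the RNG
#'   stream untouched.
#' @param checkpoint_path optional path; the network is checkpointed there
#'   every \code{log_every} iterations and at the end.
#' @param log_every iterations between checkpoints/progress messages.
#' @param verbose print progress messages.
#' @return the trained network, with the loss trace (data frame
#'   \code{iteration}, \code{area}, \code{mean_e_beta}) attached as
#'   \code{attr(, "loss_trace")}.
#' @export
train_dhpc <- function(network, images, n_iterations,
                       batch_size = NULL, seed = NULL,
                       checkpoint_path = NULL, log_every = 100L,
                       verbose = FALSE) {
  cfg <- network$config
  if (!is.null(seed)) set.seed(seed)
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 0) stop("n_iterations must be >= 0")
  if (length(dim(images)) == 3)
    images <- array(images, dim = c(dim(images)[1:2], 1, dim(images)[3]))
  n_img <- dim(images)[4]
  if (n_img < 1) stop("training dataset is empty")
  if (is.null(batch_size)) batch_size <- min(cfg$batch_size, n_img)
  if (batch_size > n_img) stop("batch_size exceeds the dataset size")

  cnt <- count_architecture(network$config)
  n_err <- cnt$connections$synapses_per_population /
    cnt$areas$population_size[-1] * cnt$areas$populations[-1]  # error components
  trace <- matrix(NA_real_, nrow = n_iterations, ncol = cfg$n_areas)
  order_pool <- integer(0)
  for (it in seq_len(n_iterations)) {
    if (length(order_pool) < batch_size) order_pool <- sample.int(n_img)
    take <- order_pool[seq_len(batch_size)]
    order_pool <- order_pool[-seq_len(batch_size)]
    state <- new_state(network, images[, , , take, drop = FALSE])
    state <- settle(state, network, record_energy = TRUE)
    e <- attr(state, "energy")
    trace[it, ] <- e[nrow(e), ] / (n_err * batch_size)
    if (!all(is.finite(trace[it, ]))) {
      if (!is.null(checkpoint_path)) save_checkpoint(network, checkpoint_path)
      stop("non-finite loss at iteration ", it,
           "; last good network checkpointed")
    }
    network <- learning_step(state, network)
    if (verbose && (it %% log_every == 0 || it == n_iterations))
      message(sprintf("iteration %d/%d  mean e_beta: %s", it, n_iterations,
                      paste(signif(trace[it, ], 4), collapse = " ")))
    if (!is.null(checkpoint_path) && it %% log_every == 0)
      save_checkpoint(network, checkpoint_path)
  }
  if (!is.null(checkpoint_path)) save_checkpoint(network, checkpoint_path)
  attr(network, "loss_trace") <- data.frame(
    iteration = rep(seq_len(n_iterations), times = cfg$n_areas),
    area = rep(seq_len(cfg$n_areas), each = n_iterations),
    mean_e_beta = as.vector(trace))
  network
}

#' Harvest settled responses into per-area response matrices
#'
#' Presents every stimulus to the network (no learning), settles with the
#' configured number of inference steps from the standard initial activity,
#' and records the resulting activities. Neurons that never respond with a
#' strictly positive activity to any stimulus are flagged inactive; due to
#' regularization and rectification such silent neurons are expected, and all
#' analysis functions exclude them.
#'
#' @param network a trained (or untrained) \code{\link{dhpc_network}}.
#' @param images stimulus array \code{H x W x C x n} (or \code{H x W x n}).
#' @param labels optional stimulus labels (length \code{n}).
#' @param batch_size stimuli settled per call; affects memory only, not the
#'   results (each stimulus settles independently).
#' @return An object of class \code{"dhpc_responses"}: list with
#'   \code{responses} (per area, an \code{n_stimuli x n_neurons} matrix;
#'   neuron index runs neuron-within-population fastest), \code{active} (per
#'   area, logical vector), \code{labels} and \code{config}.
#' @export
harvest_responses <- function(network, images, labels = NULL,
                              batch_size = NULL) {
  cfg <- network$config
  if (length(dim(images)) == 3)
    images <- array(images, dim = c(dim(images)[1:2], 1, dim(images)[3]))
  n_img <- dim(images)[4]
  if (is.null(batch_size)) batch_size <- min(cfg$batch_size, n_img)
  if (!is.null(labels) && length(labels) != n_img)
    stop("labels length does not match the number of stimuli")
  cnt <- count_architecture(cfg)
  responses <- lapply(seq_len(cfg$n_areas),
                      function(l) matrix(0, n_img, cnt$areas$neurons[l + 1]))
  start <- 1L
  while (start <= n_img) {
    take <- start:min(start + batch_size - 1L, n_img)
    state <- new_state(network, images[, , , take, drop = FALSE])
    state <- settle(state, network)
    for (l in seq_len(cfg$n_areas)) {
      y <- state$y[[l]]                        # n_l x B x P_l
      responses[[l]][take, ] <- matrix(aperm(y, c(2, 1, 3)), nrow = length(take))
    }
    start <- start + batch_size
  }
  structure(list(
    responses = responses,
    active = lapply(responses, function(m) apply(m, 2, max) > 0),
    labels = labels,
    config = cfg
  ), class = "dhpc_responses")
}

#' @export
print.dhpc_responses <- function(x, ...) {
  for (l in seq_along(x$responses))
    cat(sprintf("area %d: %d stimuli x %d neurons (%d active)\n",
                l, nrow(x$responses[[l]]), ncol(x$responses[[l]]),
                sum(x$active[[l]])))
  invisible(x)
}

#' Mean squared reconstruction error of top-down decoding
#'
#' Infers latent representations for the given images, decodes them from the
#' requested area back to the input (see \code{\link{decode_from_area}}) and
#' returns the mean squared pixel error.
#'
#' @param network the network.
#' @param images stimulus array.
#' @param area area to decode from.
#' @return scalar mean squared error.
#' @export
reconstruction_error <- function(network, images, area) {
  cfg <- network$config
  if (length(dim(images)) == 3)
    images <- array(images, dim = c(dim(images)[1:2], 1, dim(images)[3]))
  n_img <- dim(images)[4]
  bs <- min(cfg$batch_size, n_img)
  sse <- 0
  start <- 1L
  while (start <= n_img) {
    take <- start:min(start + bs - 1L, n_img)
    batch <- images[, , , take, drop = FALSE]
    state <- settle(new_state(network, batch), network)
    recon <- decode_from_area(network, state, area)
    sse <- sse + sum((recon - batch)^2)
    start <- start + bs
  }
  sse / length(images)
}
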