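#' Network configuration for a deep Hebbian predictive coding model
#'
#' Describes the static architecture and the learning/inference hyperparameters
#' of a DHPC network. Area 0 is the input: each pixel is one population whose
#' size equals the channel count, so an \code{H x W x C} image maps onto an
#' \code{H x W} grid of populations of \code{C} neurons. Every higher area
#' \code{l} is a grid of populations of \code{n_l} neurons; each population is
#' reciprocally connected to the square \code{rf_size x rf_size} block of
#' populations below it, so consecutive grids shrink by \code{rf_size - 1} per
#' dimension. In the fully connected variant each area is a single population
#' whose receptive field spans the whole area below.
#'
#' @param input_size integer vector \code{c(height, width, channels)} of the
#'   input images (channels defaults to 1 if omitted).
#' @param population_sizes integer vector: neurons per population in areas
#'   \code{1..N}.
#' @param rf_size receptive-field side length(s) \code{s_l}; a scalar is
#'   recycled across areas. Ignored when \code{fully_connected = TRUE}.
#' @param gamma_y update rate for the inference (activity) step.
#' @param gamma_w learning rate for the weight step.
#' @param alpha_y activity L1-regularization constant(s), one per area or a
#'   scalar recycled (a per-area vector expresses e.g. top-area-only
#'   regularization).
#' @param alpha_w weight L1-regularization constant.
#' @param eta weighting of top-down errors during inference, one per area or a
#'   scalar recycled; the top area receives no top-down input.
#' @param n_inference_steps inference steps run per stimulus before a weight
#'   update (and before harvesting responses).
#' @param batch_size stimuli per training batch.
#' @param init_activity value activities are reset to for each new batch.
#' @param fully_connected if \code{TRUE}, build the variant without receptive
#'   fields: one population per area spanning the entire area below.
#'
#' @return An object of class \code{"dhpc_config"}: a list with the validated
#'   hyperparameters and a \code{geometry} element, a list of per-area
#'   geometries (area 0 first) with fields \code{level}, \code{grid_rows},
#'   \code{grid_cols}, \code{rf_size}, \code{population_size}.
#' @examples
#' cfg <- dhpc_config(input_size = c(16, 16, 1), population_sizes = c(4, 8, 16),
#'                    rf_size = 5)
#' count_architecture(cfg)
#' @export
dhpc_config <- function(input_size = c(16, 16, 1),
                        population_sizes = c(4, 8, 16),
                        rf_size = 5,
                        gamma_y = 0.05,
                        gamma_w = 0.05,
                        alpha_y = 0.001,
                        alpha_w = 0.001,
                        eta = 1,
                        n_inference_steps = 20,
                        batch_size = 50,
                        init_activity = 0.1,
                        fully_connected = FALSE) {
  if (length(input_size) == 2) input_size <- c(input_size, 1L)
  if (length(input_size) != 3 || any(input_size < 1))
    stop("input_size must be c(height, width, channels) with positive entries")
  input_size <- as.integer(input_size)
  n_areas <- length(population_sizes)
  if (n_areas < 1) stop("at least one area above the input is required")
  population_sizes <- as.integer(population_sizes)
  if (any(population_sizes < 1)) stop("population sizes must be >= 1")
  if (gamma_y <= 0 || gamma_w <= 0) stop("gamma_y and gamma_w must be > 0")
  alpha_y <- rep_len(as.numeric(alpha_y), n_areas)
  eta <- rep_len(as.numeric(eta), n_areas)
  if (any(alpha_y < 0) || alpha_w < 0 || any(eta < 0))
    stop("alpha_y, alpha_w and eta must be >= 0")
  if (n_inference_steps < 1 || batch_size < 1)
    stop("n_inference_steps and batch_size must be >= 1")

  geometry <- vector("list", n_areas + 1L)
  geometry[[1]] <- list(level = 0L, grid_rows = input_size[1],
                        grid_cols = input_size[2], rf_size = NA_integer_,
                        population_size = input_size[3])
  if (fully_connected) {
    rf_size <- integer(n_areas)
  } else {
    rf_size <- as.integer(rep_len(rf_size, n_areas))
    if (any(rf_size < 1)) stop("rf_size must be >= 1")
  }
  for (l in seq_len(n_areas)) {
    below <- geometry[[l]]
    if (fully_connected) {
      # the whole lower grid is the receptive field => a single population
      if (below$grid_rows != below$grid_cols && l > 1)
        stop("fully connected variant requires square grids")
      rf_size[l] <- below$grid_rows
      if (below$grid_rows != below$grid_cols)
        stop("fully connected variant requires square input")
    }
    gr <- below$grid_rows - (rf_size[l] - 1L)
    gc <- below$grid_cols - (rf_size[l] - 1L)
    if (gr < 1 || gc < 1)
      stop(sprintf("rf_size %d leaves no populations in area %d", rf_size[l], l))
    geometry[[l + 1]] <- list(level = l, grid_rows = gr, grid_cols = gc,
                              rf_size = rf_size[l],
                              population_size = population_sizes[l])
  }

  structure(list(
    input_size = input_size,
    n_areas = n_areas,
    geometry = geometry,
    rf_size = rf_size,
    population_sizes = population_sizes,
    gamma_y = gamma_y, gamma_w = gamma_w,
    alpha_y = alpha_y, alpha_w = alpha_w, eta = eta,
    n_inference_steps = as.integer(n_inference_steps),
    batch_size = as.integer(batch_size),
    init_activity = init_activity,
    fully_connected = isTRUE(fully_connected)
  ), class = "dhpc_config")
}

#' Default configuration of the desk-scale emergence study
#'
#' The calibrated three-area network used by the package's emergence study
#' and worked examples: 16 x 16 grayscale input, receptive fields of 5,
#' populations of 4/8/16 neurons, batch 50. Relative to the generic
#' full-scale defaults of \code{\link{dhpc_config}}, the desk-scale study
#' uses a higher learning rate (compressing the long training schedule of the
#' full-scale model into a few thousand iterations), down-weighted top-down
#' errors (\code{eta = 0.35}) and extra activity regularization in the top
#' area — the configuration regime in which the hierarchy effects under study
#' (selectivity increasing with depth, decodable top-area representations,
#' reconstructable inputs) develop within a desk-scale training budget; see
#' the methods vignette for the calibration rationale.
#'
#' @param ... overrides passed on to \code{\link{dhpc_config}}.
#' @return a \code{dhpc_config}.
#' @export
default_study_config <- function(...) {
  args <- utils::modifyList(list(
    input_size = c(16, 16, 1),
    population_sizes = c(4, 8, 16),
    rf_size = 5,
    gamma_y = 0.05,
    gamma_w = 0.2,
    alpha_y = c(0.001, 0.001, 0.005),
    alpha_w = 0.001,
    eta = 0.35,
    n_inference_steps = 30,
    batch_size = 50
  ), list(...))
  do.call(dhpc_config, args)
}

#' @export
print.dhpc_config <- function(x, ...) {
  cat(sprintf("DHPC network config: %d area(s) above a %dx%dx%d input%s\n",
              x$n_areas, x$input_size[1], x$input_size[2], x$input_size[3],
              if (x$fully_connected) " (fully connected)" else ""))
  tab <- count_architecture(x)
  print(tab$areas, row.names = FALSE)
  print(tab$connections, row.names = FALSE)
  invisible(x)
}

# number of populations in area l (0-based level index)
n_populations <- function(config, level) {
  g <- config$geometry[[level + 1L]]
  g$grid_rows * g$grid_cols
}

#' Architecture bookkeeping: populations, neurons and synapse counts
#'
#' Tallies, for each area, the number of populations (grid positions) and
#' neurons, and for each pair of consecutive areas the number of stored
#' interareal weights. Feedback (prediction) and feedforward (error) synapses
#' share the same stored weight, so the feedforward count equals the feedback
#' count: \code{populations_l * rf_size_l^2 * n_(l-1) * n_l}.
#'
#' @param config a \code{\link{dhpc_config}}.
#' @return A list with data frames \code{areas} (level, grid, populations,
#'   population_size, neurons) and \code{connections} (lower, upper,
#'   synapses_per_population, synapses).
#' @export
count_architecture <- function(config) {
  stopifnot(inherits(config, "dhpc_config"))
  geo <- config$geometry
  areas <- do.call(rbind, lapply(geo, function(g) data.frame(
    level = g$level, grid_rows = g$grid_rows, grid_cols = g$grid_cols,
    populations = g$grid_rows * g$grid_cols,
    population_size = g$population_size,
    neurons = g$grid_rows * g$grid_cols * g$population_size)))
  conns <- do.call(rbind, lapply(seq_len(config$n_areas), function(l) {
    lo <- geo[[l]]; up <- geo[[l + 1]]
    per_pop <- up$rf_size^2 * lo$population_size * up$population_size
    data.frame(lower = l - 1L, upper = l,
               synapses_per_population = per_pop,
               synapses = (up$grid_rows * up$grid_cols) * per_pop)
  }))
  list(areas = areas, connections = conns)
}

# receptive-field index map for area pair (l-1, l): an s^2 x P_l integer matrix
# whose column k lists the lower-area population indices covered by the RF of
# upper population k. Populations and RF offsets are both column-major
# (row index fastest), matching R array layout.
rf_index_map <- function(config, level) {
  up <- config$geometry[[level + 1L]]
  lo <- config$geometry[[level]]
  s <- up$rf_size
  Pu <- up$grid_rows * up$grid_cols
  idx <- matrix(0L, nrow = s * s, ncol = Pu)
  for (k in seq_len(Pu)) {
    r <- (k - 1L) %% up$grid_rows + 1L
    c <- (k - 1L) %/% up$grid_rows + 1L
    q <- 1L
    for (qc in 0:(s - 1L)) for (qr in 0:(s - 1L)) {
      idx[q, k] <- (c - 1L + qc) * lo$grid_rows + (r + qr)
      q <- q + 1L
    }
  }
  idx
}
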