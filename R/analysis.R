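#' Excess kurtosis (population-moment convention)
#'
#' \code{kappa = sum((x - mean(x))^4) / (N * s^4) - 3} with the population
#' standard deviation (denominator \code{N}). Used throughout as the measure
#' of image selectivity (kurtosis of one neuron's responses across stimuli)
#' and population sparseness (kurtosis across neurons for one stimulus):
#' high kurtosis means a heavy-tailed response distribution, i.e. strong
#' responses to few stimuli/neurons.
#'
#' @param x numeric vector of at least 4 observations.
#' @return scalar excess kurtosis; \code{NA} when the variance is zero (the
#'   statistic is undefined for constant input).
#' @examples
#' excess_kurtosis(c(1, -1, 1, -1))  # -2
#' @export
excess_kurtosis <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("excess kurtosis needs at least 4 observations")
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) return(NA_real_)
  mean((x - m)^4) / v^2 - 3
}

# active-neuron response matrix for one area
active_responses <- function(responses, area) {
  stopifnot(inherits(responses, "dhpc_responses"))
  m <- responses$responses[[area]]
  m[, responses$active[[area]], drop = FALSE]
}

#' Image selectivity per neuron
#'
#' Excess kurtosis of each active neuron's responses across all stimuli.
#' Neurons with constant responses yield \code{NA}.
#'
#' @param responses a \code{\link{harvest_responses}} result.
#' @param area area index.
#' @return numeric vector, one value per active neuron.
#' @export
selectivity <- function(responses, area) {
  m <- active_responses(responses, area)
  if (nrow(m) < 4) stop("selectivity needs at least 4 stimuli")
  apply(m, 2, excess_kurtosis)
}

#' Population sparseness per stimulus
#'
#' Each active neuron's responses are first divided by that neuron's mean
#' response across stimuli, so that differences in average firing rate do not
#' masquerade as sparseness; excess kurtosis is then computed per stimulus
#' across the normalized neurons.
#'
#' @inheritParams selectivity
#' @return numeric vector, one value per stimulus.
#' @export
sparseness <- function(responses, area) {
  m <- active_responses(responses, area)
  if (ncol(m) < 4) stop("sparseness needs at least 4 active neurons")
  sparseness_matrix(m)
}

sparseness_matrix <- function(m) {
  mu <- colMeans(m)
  keep <- mu > 0
  m <- sweep(m[, keep, drop = FALSE], 2, mu[keep], "/")
  apply(m, 1, excess_kurtosis)
}

#' Dynamic range (interquartile range) per neuron
#'
#' 75th minus 25th percentile of each active neuron's responses across
#' stimuli, with linear-interpolation percentiles.
#'
#' @inheritParams selectivity
#' @return numeric vector, one value per active neuron.
#' @export
dynamic_range <- function(responses, area) {
  m <- active_responses(responses, area)
  if (nrow(m) < 4) stop("dynamic range needs at least 4 stimuli")
  apply(m, 2, function(x) unname(diff(stats::quantile(x, c(0.25, 0.75),
                                                      type = 7))))
}

#' Sparseness after ablating selective or broad-dynamic-range neurons
#'
#' Recomputes population sparseness after removing the top fraction of active
#' neurons ranked by selectivity (\code{"snr"}, Selective Neurons Removed) or
#' by interquartile range (\code{"dnr"}, Dynamic-range Neurons Removed);
#' \code{"all"} keeps every active neuron and equals
#' \code{\link{sparseness}}.
#'
#' @inheritParams selectivity
#' @param mode \code{"all"}, \code{"snr"} or \code{"dnr"}.
#' @param fraction fraction of active neurons to remove (default 0.10).
#' @return numeric vector of per-stimulus sparseness on the retained neurons.
#' @export
ablation_sparseness <- function(responses, area,
                                mode = c("all", "snr", "dnr"),
                                fraction = 0.10) {
  mode <- match.arg(mode)
  m <- active_responses(responses, area)
  if (mode != "all" && fraction > 0) {
    score <- switch(mode,
      snr = {
        s <- apply(m, 2, excess_kurtosis)
        s[is.na(s)] <- -Inf
        s
      },
      dnr = apply(m, 2, function(x)
        unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))))
    n_drop <- floor(fraction * ncol(m))
    if (n_drop > 0)
      m <- m[, -order(score, decreasing = TRUE)[seq_len(n_drop)],
             drop = FALSE]
  }
  if (ncol(m) < 4) stop("fewer than 4 neurons retained after ablation")
  sparseness_matrix(m)
}

#' Correlations of selectivity and sparseness with mean activity
#'
#' Pearson correlation between the log of selectivity and each neuron's mean
#' response, and between per-stimulus sparseness and the mean population
#' response to that stimulus. Since excess kurtosis can be negative, the log
#' is taken of the non-excess kurtosis \code{kappa + 3} (positive whenever
#' the variance exists).
#'
#' @inheritParams selectivity
#' @return list with \code{r_selectivity_activity} and
#'   \code{r_sparseness_activity} (either may be \code{NA} when degenerate).
#' @export
activity_correlations <- function(responses, area) {
  m <- active_responses(responses, area)
  sel <- apply(m, 2, excess_kurtosis)
  mean_rate <- colMeans(m)
  ok <- !is.na(sel) & sel > -3
  r1 <- if (sum(ok) >= 3 && stats::sd(log(sel[ok] + 3)) > 0 &&
            stats::sd(mean_rate[ok]) > 0)
    stats::cor(log(sel[ok] + 3), mean_rate[ok]) else NA_real_
  sp <- sparseness_matrix(m)
  pop_rate <- rowMeans(m)
  ok2 <- !is.na(sp)
  r2 <- if (sum(ok2) >= 3 && stats::sd(sp[ok2]) > 0 &&
            stats::sd(pop_rate[ok2]) > 0)
    stats::cor(sp[ok2], pop_rate[ok2]) else NA_real_
  list(r_selectivity_activity = r1, r_sparseness_activity = r2)
}

#' Pairwise area comparisons (Mann-Whitney U, Bonferroni-corrected)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests between every pair of
#' areas, with p-values multiplied by the number of pairs and capped at 1.
#'
#' @param values named list of numeric vectors, one per area (\code{NA}s are
#'   dropped).
#' @return data frame with columns \code{area_a}, \code{area_b},
#'   \code{statistic}, \code{p_raw}, \code{p_bonferroni}.
#' @export
compare_areas <- function(values) {
  stopifnot(is.list(values), length(values) >= 2)
  if (is.null(names(values))) names(values) <- seq_along(values)
  pairs <- utils::combn(length(values), 2)
  res <- apply(pairs, 2, function(ij) {
    a <- values[[ij[1]]]; b <- values[[ij[2]]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
    c(statistic = unname(wt$statistic), p = wt$p.value)
  })
  data.frame(area_a = names(values)[pairs[1, ]],
             area_b = names(values)[pairs[2, ]],
             statistic = res["statistic", ],
             p_raw = res["p", ],
             p_bonferroni = pmin(1, res["p", ] * ncol(pairs)))
}

#' Linear readout of object class from area representations
#'
#' Trains a linear binary SVM (cost = 1) on the settled activity vectors of
#' each area and evaluates held-out accuracy, repeated over bootstrap splits:
#' each repeat draws a fresh training subset without replacement and tests on
#' the complement. A one-sample t-test of the accuracies against chance (0.5)
#' is reported per area.
#'
#' @param responses a \code{\link{harvest_responses}} result with binary
#'   \code{labels}.
#' @param train_fraction fraction of stimuli used for fitting when
#'   \code{n_train} is not given (default 0.75).
#' @param n_boot number of bootstrap repeats (default 100).
#' @param n_train number of training stimuli per repeat; overrides
#'   \code{train_fraction}.
#' @param seed optional seed for the splits.
#' @return list with \code{accuracy} (matrix \code{n_boot x n_areas}),
#'   \code{mean_accuracy}, and \code{p_vs_chance} per area.
#' @export
linear_readout <- function(responses, train_fraction = 0.75, n_boot = 100L,
                           n_train = NULL, seed = NULL) {
  stopifnot(inherits(responses, "dhpc_responses"))
  labels <- responses$labels
  if (is.null(labels)) stop("responses carry no stimulus labels")
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("linear readout requires binary labels")
  n <- length(labels)
  if (is.null(n_train)) n_train <- round(train_fraction * n)
  if (n_train < 2 || n_train >= n) stop("invalid training-set size")
  if (!is.null(seed)) set.seed(seed)
  n_areas <- length(responses$responses)
  acc <- matrix(NA_real_, n_boot, n_areas)
  for (b in seq_len(n_boot)) {
    repeat {
      tr <- sample.int(n, n_train)
      if (nlevels(droplevels(labels[tr])) == 2) break
      warning("single-class training sample drawn; resampling")
    }
    for (l in seq_len(n_areas)) {
      m <- responses$responses[[l]][, responses$active[[l]], drop = FALSE]
      # standardize by training-set statistics: activity scales differ by
      # orders of magnitude across areas and libsvm's fixed cost is not
      # scale-free
      mu <- colMeans(m[tr, , drop = FALSE])
      sdev <- apply(m[tr, , drop = FALSE], 2, stats::sd)
      sdev[sdev == 0] <- 1
      z <- sweep(sweep(m, 2, mu), 2, sdev, "/")
      fit <- e1071::svm(x = z[tr, , drop = FALSE], y = labels[tr],
                        kernel = "linear", cost = 1, scale = FALSE)
      pred <- stats::predict(fit, z[-tr, , drop = FALSE])
      acc[b, l] <- mean(pred == labels[-tr])
    }
  }
  p <- apply(acc, 2, function(a) {
    if (length(a) < 2) NA_real_
    else if (stats::sd(a) == 0) as.numeric(mean(a) == 0.5)  # degenerate: all repeats equal
    else stats::t.test(a, mu = 0.5)$p.value
  })
  list(accuracy = acc, mean_accuracy = colMeans(acc), p_vs_chance = p)
}

#' Receptive-field weight images of area-1 neurons
#'
#' Renders the feedback weights from selected area-1 neurons onto their
#' area-0 receptive field as images: each neuron's weight slice is min-max
#' normalized to \code{[0, 1]} and reshaped to
#' \code{rf_size x rf_size x channels}. After training on images with
#' naturalistic statistics these resemble oriented Gabor-like filters.
#'
#' @param network a trained \code{\link{dhpc_network}}.
#' @param area source area (the weights to \code{area - 1} are rendered);
#'   area 1 gives pixel-space filters.
#' @param neurons data frame-free specification: either \code{NULL} (all
#'   neurons of the first population), or a 2-column matrix/data.frame of
#'   (population, neuron) indices.
#' @return list of arrays \code{rf_size x rf_size x channels} in
#'   \code{[0, 1]}; constant weight slices map to an all-0.5 image.
#' @export
rf_weight_images <- function(network, area = 1L, neurons = NULL) {
  cfg <- network$config
  W <- network$weights[[area]]
  lo <- cfg$geometry[[area]]
  up <- cfg$geometry[[area + 1]]
  s <- up$rf_size; n_low <- lo$population_size
  if (is.null(neurons))
    neurons <- cbind(1L, seq_len(up$population_size))
  neurons <- as.matrix(neurons)
  lapply(seq_len(nrow(neurons)), function(i) {
    k <- neurons[i, 1]; j <- neurons[i, 2]
    w <- W[, j, k]                        # length s^2 * n_low
    rng <- range(w)
    w <- if (rng[1] == rng[2]) rep(0.5, length(w))
         else (w - rng[1]) / (rng[2] - rng[1])
    # rows are lower-neuron fastest within column-major RF offsets
    img <- aperm(array(w, dim = c(n_low, s, s)), c(2, 3, 1))
    img
  })
}

#' Full response-property report for a harvested network
#'
#' Bundles every per-area statistic: selectivity, sparseness, dynamic range,
#' ablation sparseness (All/SNR/DNR), activity correlations, pairwise
#' Mann-Whitney area comparisons of selectivity and sparseness, and (when
#' labels are present) the linear readout.
#'
#' @param responses a \code{\link{harvest_responses}} result.
#' @param n_boot bootstrap repeats for the readout.
#' @param ablation_fraction fraction removed in the SNR/DNR ablations.
#' @param seed seed for the readout splits.
#' @return An object of class \code{"dhpc_metrics"} (a nested list).
#' @export
metrics_report <- function(responses, n_boot = 100L, ablation_fraction = 0.10,
                           seed = NULL) {
  n_areas <- length(responses$responses)
  per_area <- lapply(seq_len(n_areas), function(l) {
    m <- active_responses(responses, l)
    list(
      n_active = ncol(m),
      selectivity = selectivity(responses, l),
      sparseness = sparseness(responses, l),
      dynamic_range = dynamic_range(responses, l),
      ablation = list(
        all = ablation_sparseness(responses, l, "all"),
        snr = ablation_sparseness(responses, l, "snr", ablation_fraction),
        dnr = ablation_sparseness(responses, l, "dnr", ablation_fraction)),
      correlations = activity_correlations(responses, l),
      mean_rate_per_neuron = colMeans(m),
      mean_rate_per_stimulus = rowMeans(m))
  })
  names(per_area) <- paste0("area", seq_len(n_areas))
  out <- list(
    per_area = per_area,
    selectivity_comparison = compare_areas(
      lapply(per_area, function(a) a$selectivity)),
    sparseness_comparison = compare_areas(
      lapply(per_area, function(a) a$sparseness)))
  if (!is.null(responses$labels))
    out$readout <- linear_readout(responses, n_boot = n_boot, seed = seed)
  structure(out, class = "dhpc_metrics")
}

#' @export
print.dhpc_metrics <- function(x, ...) {
  for (nm in names(x$per_area)) {
    a <- x$per_area[[nm]]
    cat(sprintf(
      "%s: %d active neurons | mean selectivity %.3f | mean sparseness %.3f | mean IQR %.3f\n",
      nm, a$n_active, mean(a$selectivity, na.rm = TRUE),
      mean(a$sparseness, na.rm = TRUE), mean(a$dynamic_range)))
  }
  if (!is.null(x$readout))
    cat("readout accuracy:",
        paste(sprintf("%.3f", x$readout$mean_accuracy), collapse = " "), "\n")
  invisible(x)
}
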