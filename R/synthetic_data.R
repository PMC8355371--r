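#' Specification of a synthetic two-class image set
#'
#' The generator emulates the image statistics the network exploits: a
#' 1/f-filtered noise background (the spectral signature of natural images)
#' with oriented Gabor patches composited on top. The two classes differ in
#' the orientation and layout of their patches: class \code{"a"} carries
#' horizontally biased structure at two fixed (jittered) anchor positions,
#' class \code{"b"} vertically biased structure, and every image additionally
#' receives several randomly placed, randomly oriented clutter patches. The
#' partly consistent layout mirrors the way real object classes share coarse
#' spatial structure across exemplars and makes the classes linearly
#' discriminable from raw pixels, while the clutter provides the dense
#' oriented structure of natural scenes.
#'
#' @param image_size side length of the square images (pixels).
#' @param channels 1 (grayscale) or 3 (RGB; the pattern is shared across
#'   channels with small independent color jitter).
#' @param n_per_class images per class, recycled to length 2.
#' @param background_exponent spectral exponent of the 1/f^exponent
#'   background.
#' @param background_amplitude standard deviation of the background around
#'   mid-gray. Together with the pose jitter defaults this places raw-pixel
#'   linear separability of the two classes in the high 0.8s — above chance
#'   with a clear margin but off the ceiling, as for natural-image object
#'   classes.
#' @param patch_amplitude peak amplitude of the Gabor patches.
#' @param patch_sd Gaussian envelope SD of the patches (pixels).
#' @param wavelength carrier wavelength range of the patches (pixels); each
#'   patch draws its wavelength uniformly from this range, giving the
#'   multi-scale structure of natural images (a scalar fixes it).
#' @param orientation_sd jitter (degrees) around each class's preferred
#'   orientation (0 = horizontal structure for class a, 90 for class b).
#' @param position_jitter anchor position jitter (pixels).
#' @param n_distractors randomly placed, randomly oriented clutter patches
#'   per image (class-independent), giving the dense oriented structure of
#'   natural scenes.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return object of class \code{"dhpc_synthetic_spec"}.
#' @export
synthetic_spec <- function(image_size = 16L, channels = 1L,
                           n_per_class = c(200L, 200L),
                           background_exponent = 1.0,
                           background_amplitude = 0.08,
                           patch_amplitude = 0.45,
                           patch_sd = 2.2,
                           wavelength = c(4, 8),
                           orientation_sd = 12,
                           position_jitter = 2.0,
                           n_distractors = 4L,
                           seed = 1L) {
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3")
  if (image_size < 4) stop("image_size must be >= 4")
  n_per_class <- as.integer(rep_len(n_per_class, 2))
  if (any(n_per_class < 1)) stop("n_per_class must be >= 1")
  structure(list(image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 n_per_class = n_per_class,
                 background_exponent = background_exponent,
                 background_amplitude = background_amplitude,
                 patch_amplitude = patch_amplitude,
                 patch_sd = patch_sd,
                 wavelength = range(rep_len(as.numeric(wavelength), 2)),
                 orientation_sd = orientation_sd,
                 position_jitter = position_jitter,
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "dhpc_synthetic_spec")
}

# DFT sample frequencies in cycles/pixel
fft_frequencies <- function(n) {
  k <- 0:(n - 1)
  ifelse(k > n / 2, k - n, k) / n
}

# even-symmetric Gabor patch evaluated over the full image grid
gabor_patch <- function(size, cx, cy, theta, sd, wavelength, amplitude) {
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  x <- g$c - cx; y <- g$r - cy
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  patch <- amplitude * exp(-(xr^2 + yr^2) / (2 * sd^2)) *
    cos(2 * pi * xr / wavelength)
  matrix(patch, size, size)
}

# 1/f^exponent filtered Gaussian noise, zero mean, unit sd
spectral_noise <- function(size, exponent) {
  z <- matrix(stats::rnorm(size * size), size, size)
  f <- stats::fft(z)
  fr <- fft_frequencies(size)
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  amp <- ifelse(rad == 0, 0, 1 / rad^exponent)
  bg <- Re(stats::fft(f * amp, inverse = TRUE)) / (size * size)
  bg / stats::sd(bg)
}

#' Generate a labeled synthetic image set
#'
#' Deterministic given the spec (including its seed). Class \code{"a"}
#' images carry horizontally biased oriented structure, class \code{"b"}
#' vertically biased structure, over a 1/f background; pixel values are
#' clipped to \code{[0, 1]}.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{images} (array \code{size x size x channels x n})
#'   and \code{labels} (factor \code{"a"}/\code{"b"}, classes interleaved by
#'   block: all of class a, then all of class b).
#' @export
generate_images <- function(spec) {
  stopifnot(inherits(spec, "dhpc_synthetic_spec"))
  set.seed(spec$seed)
  n <- sum(spec$n_per_class)
  sz <- spec$image_size
  images <- array(0, dim = c(sz, sz, spec$channels, n))
  labels <- factor(rep(c("a", "b"), spec$n_per_class), levels = c("a", "b"))
  third <- sz / 3
  for (i in seq_len(n)) {
    horizontal <- labels[i] == "a"
    base_theta <- if (horizontal) 0 else pi / 2
    img <- 0.5 + spec$background_amplitude *
      spectral_noise(sz, spec$background_exponent)
    # two class-anchored patches: for horizontal structure they sit at 1/3 and
    # 2/3 of the height (extending along rows); for vertical, of the width
    for (anchor in c(third, 2 * third)) {
      jx <- stats::runif(1, -spec$position_jitter, spec$position_jitter)
      jy <- stats::runif(1, -spec$position_jitter, spec$position_jitter)
      theta <- base_theta + stats::rnorm(1, 0, spec$orientation_sd * pi / 180)
      if (horizontal) { cy <- anchor + jy; cx <- sz / 2 + jx }
      else            { cx <- anchor + jx; cy <- sz / 2 + jy }
      img <- img + gabor_patch(sz, cx, cy, theta, spec$patch_sd,
                               stats::runif(1, spec$wavelength[1],
                                            spec$wavelength[2]),
                               spec$patch_amplitude)
    }
    # randomly placed, randomly oriented clutter patches: natural images carry
    # oriented structure everywhere, not only on the object
    for (d in seq_len(spec$n_distractors))
      img <- img + gabor_patch(sz, stats::runif(1, 1, sz),
                               stats::runif(1, 1, sz),
                               stats::runif(1, 0, pi), spec$patch_sd,
                               stats::runif(1, spec$wavelength[1],
                                            spec$wavelength[2]),
                               spec$patch_amplitude * stats::runif(1, 0.5, 1))
    img <- pmin(pmax(img, 0), 1)
    for (ch in seq_len(spec$channels)) {
      jitter <- if (spec$channels > 1) stats::runif(1, 0.9, 1.1) else 1
      images[, , ch, i] <- pmin(pmax(img * jitter, 0), 1)
    }
  }
  list(images = images, labels = labels)
}

#' Write an image set as PNG files plus a labels table
#'
#' @param images array \code{H x W x C x n} with values in \code{[0, 1]}.
#' @param labels optional labels (length \code{n}).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_image_dir <- function(images, labels = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- dim(images)[4]
  paths <- file.path(dir, sprintf("stim_%05d.png", seq_len(n)))
  for (i in seq_len(n)) {
    img <- images[, , , i]
    if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
    png::writePNG(img, paths[i])
  }
  if (!is.null(labels))
    utils::write.csv(data.frame(file = basename(paths),
                                label = as.character(labels)),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(paths)
}

#' Read an image set from a directory of PNG files
#'
#' Reads every \code{.png} in the directory (sorted by name), scaled to
#' \code{[0, 1]}; labels are taken from \code{labels.csv} (columns
#' \code{file}, \code{label}) when present.
#'
#' @param dir directory path.
#' @return list with \code{images} (array \code{H x W x C x n}) and
#'   \code{labels} (factor or \code{NULL}).
#' @export
read_image_dir <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG images found in ", dir)
  imgs <- lapply(files, png::readPNG)
  d <- dim(imgs[[1]])
  if (length(d) == 2) d <- c(d, 1L)
  images <- array(0, dim = c(d[1], d[2], d[3], length(files)))
  for (i in seq_along(imgs)) images[, , , i] <- imgs[[i]]
  labels <- NULL
  lab_file <- file.path(dir, "labels.csv")
  if (file.exists(lab_file)) {
    lab <- utils::read.csv(lab_file, stringsAsFactors = FALSE)
    labels <- factor(lab$label[match(basename(files), lab$file)])
  }
  list(images = images, labels = labels)
}

#' Read CIFAR-10 binary batch files
#'
#' Parses the published binary layout: 3073-byte records of one label byte
#' followed by 3072 pixel bytes (three 1024-byte channel planes, row-major
#' 32x32). Pixels are scaled to \code{[0, 1]}.
#'
#' @param files one or more batch file paths.
#' @param labels_keep optional integer labels to retain (e.g. \code{c(0, 1)}
#'   for airplane/automobile).
#' @return list with \code{images} (array \code{32 x 32 x 3 x n}) and
#'   \code{labels} (integer vector).
#' @export
read_cifar10 <- function(files, labels_keep = NULL) {
  rec <- 3073L
  all_img <- list(); all_lab <- integer(0)
  for (f in files) {
    if (!file.exists(f)) stop("no such file: ", f)
    raw <- readBin(f, what = "raw", n = file.info(f)$size)
    if (length(raw) == 0 || length(raw) %% rec != 0)
      stop(sprintf("malformed CIFAR-10 file %s: %d bytes is not a multiple of %d (offset %d)",
                   f, length(raw), rec, length(raw) %/% rec * rec))
    n <- length(raw) %/% rec
    m <- matrix(as.integer(raw), nrow = rec)
    labs <- m[1, ]
    px <- m[-1, , drop = FALSE] / 255
    # per record: 3 channel planes of 1024 bytes, each row-major 32x32
    img <- array(px, dim = c(32, 32, 3, n))        # (col, row, ch, n) so far
    img <- aperm(img, c(2, 1, 3, 4))               # row-major -> (row, col)
    all_img[[length(all_img) + 1]] <- img
    all_lab <- c(all_lab, labs)
  }
  images <- array(unlist(all_img), dim = c(32, 32, 3, length(all_lab)))
  if (!is.null(labels_keep)) {
    keep <- all_lab %in% labels_keep
    images <- images[, , , keep, drop = FALSE]
    all_lab <- all_lab[keep]
  }
  list(images = images, labels = all_lab)
}

#' Radially averaged power spectrum of an image set
#'
#' Mean squared FFT magnitude binned by radial spatial frequency, averaged
#' over images; used to verify that generated images carry the decreasing
#' (naturalistic) power spectrum the model's emergent oriented filters depend
#' on.
#'
#' @param images array \code{H x W x C x n} (channels are averaged first).
#' @param n_bins number of radial frequency bins.
#' @return data frame with \code{frequency} (bin center, cycles/pixel) and
#'   \code{power} (mean over images), DC excluded.
#' @export
radial_power_spectrum <- function(images, n_bins = 6L) {
  sz <- dim(images)[1]
  n <- dim(images)[4]
  fr <- fft_frequencies(sz)
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  pow <- matrix(0, sz, sz)
  for (i in seq_len(n)) {
    img <- apply(images[, , , i, drop = FALSE], c(1, 2), mean)
    img <- img - mean(img)
    pow <- pow + Mod(stats::fft(img))^2
  }
  pow <- pow / n
  keep <- rad > 0
  bins <- cut(rad[keep], breaks = seq(0, max(rad), length.out = n_bins + 1))
  data.frame(
    frequency = tapply(rad[keep], bins, mean),
    power = tapply(pow[keep], bins, mean))
}
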