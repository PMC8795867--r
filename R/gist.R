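#' GIST descriptor configuration
#'
#' Settings for the spatial-envelope (GIST) descriptor: a bank of oriented
#' Gabor transfer functions applied in the frequency domain at several spatial
#' scales, whose filter-energy images are average-pooled over a coarse spatial
#' grid. The default configuration (4 scales x 8 orientations x 4x4 grid at a
#' 128x128 resize) yields the canonical 512-dimensional descriptor.
#'
#' @param image_side Square resize target in pixels (default 128).
#' @param n_scales Number of spatial-frequency scales (default 4).
#' @param n_orientations Orientations per scale (default 8).
#' @param grid Pooling cells per axis (default 4; 4x4 = 16 blocks).
#' @param prefilter_cycles Cutoff, in cycles/image, of the low-pass filter used
#'   for local contrast normalization (default 4).
#' @param normalize L2-normalize each descriptor (default TRUE). Unit-norm
#'   features stabilize the reconstruction/regularization balance in training.
#' @return A `gist_config` list. Descriptor length is
#'   `n_scales * n_orientations * grid^2`.
#' @export
gist_config <- function(image_side = 128L, n_scales = 4L, n_orientations = 8L,
                        grid = 4L, prefilter_cycles = 4, normalize = TRUE) {
  cfg <- list(
    image_side = as.integer(image_side), n_scales = as.integer(n_scales),
    n_orientations = as.integer(n_orientations), grid = as.integer(grid),
    prefilter_cycles = as.numeric(prefilter_cycles), normalize = isTRUE(normalize)
  )
  if (any(vapply(cfg[1:4], function(v) v < 1L, logical(1)))) {
    srdml_stop("all gist_config counts must be >= 1")
  }
  if (cfg$prefilter_cycles <= 0) srdml_stop("prefilter_cycles must be positive")
  structure(cfg, class = "gist_config")
}

gist_length <- function(config) {
  config$n_scales * config$n_orientations * config$grid^2
}

# FFT-ordered frequency coordinates (cycles/image) for an n x n grid.
freq_grid <- function(n) {
  f <- ((seq_len(n) - 1 + floor(n / 2)) %% n) - floor(n / 2)
  fx <- matrix(f, n, n)          # varies down rows
  fy <- matrix(f, n, n, byrow = TRUE)
  list(fx = fx, fy = fy, fr = sqrt(fx^2 + fy^2), t = atan2(fy, fx))
}

#' Build the frequency-domain Gabor filter bank
#'
#' Constructs `n_scales * n_orientations` real, nonnegative transfer functions
#' on an `image_side` squared frequency grid (FFT layout), each peak-normalized
#' to 1. Radial centers fall off geometrically with scale (factor 1.85) from
#' 0.3 cycles/pixel; angular bandwidth tightens with the number of
#' orientations, following the standard spatial-envelope construction.
#'
#' @param config A [gist_config()].
#' @return A list of `image_side` x `image_side` matrices, ordered
#'   scale-major (scale 1 orientations first).
#' @export
build_filter_bank <- function(config = gist_config()) {
  stopifnot(inherits(config, "gist_config"))
  n <- config$image_side
  if (n < 2L) srdml_stop("image_side must be at least 2")
  g <- freq_grid(n)
  fr_norm <- g$fr / n
  filters <- vector("list", config$n_scales * config$n_orientations)
  idx <- 1L
  for (s in seq_len(config$n_scales)) {
    f0 <- 0.3 / (1.85^(s - 1))                      # radial center, cycles/pixel
    ab <- 16 * config$n_orientations^2 / 32^2        # angular concentration
    for (o in seq_len(config$n_orientations)) {
      ang <- pi / config$n_orientations * (o - 1)
      tr <- g$t + ang
      tr <- tr + 2 * pi * (tr < -pi) - 2 * pi * (tr > pi)
      G <- exp(-10 * 0.35 * (fr_norm / f0 - 1)^2 - 2 * ab * pi * tr^2)
      filters[[idx]] <- G / max(G)
      idx <- idx + 1L
    }
  }
  filters
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (is.array(image) && length(dim(image)) == 3) {
    nc <- dim(image)[3]
    if (nc == 3) {
      # Rec. 709 luminance
      return(0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3])
    }
    return(apply(image, c(1, 2), mean))
  }
  srdml_stop("image must be a 2-D matrix or a 3-D (H x W x C) array")
}

#' Read an image file as a grayscale intensity matrix
#'
#' Reads PNG/JPEG/TIFF via EBImage and converts color images to luminance.
#'
#' @param path Image file path.
#' @return A numeric intensity matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) srdml_stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) dat <- aperm(dat, c(2, 1, 3)) else dat <- t(dat)
  to_grayscale(dat)
}

#' Preprocess an image for GIST extraction
#'
#' Converts to grayscale, resizes to `image_side` squared (bilinear), rescales
#' intensities to \[0, 1\], then applies local contrast normalization: the
#' low-pass component (Gaussian transfer with cutoff `prefilter_cycles`
#' cycles/image) is subtracted and the result divided by a local
#' standard-deviation envelope estimated with the same low-pass filter.
#' A constant image yields an all-zero output.
#'
#' @param image 2-D intensity matrix (any range) or 3-D color array.
#' @param config A [gist_config()].
#' @return An `image_side` x `image_side` numeric matrix.
#' @export
preprocess_image <- function(image, config = gist_config()) {
  stopifnot(inherits(config, "gist_config"))
  im <- to_grayscale(image)
  if (length(im) == 0 || nrow(im) < 2 || ncol(im) < 2) {
    srdml_stop("image must have at least 2x2 pixels")
  }
  if (all(is.na(im))) srdml_stop("image is all-NA")
  if (anyNA(im) || any(!is.finite(im))) srdml_stop("image contains non-finite pixels")
  n <- config$image_side
  if (nrow(im) != n || ncol(im) != n) {
    im <- EBImage::imageData(EBImage::resize(EBImage::Image(im), w = n, h = n))
  }
  rng <- range(im)
  im <- if (rng[2] > rng[1]) (im - rng[1]) / (rng[2] - rng[1]) else im * 0
  # low-pass Gaussian transfer, cutoff at prefilter_cycles cycles/image
  g <- freq_grid(n)
  s1 <- config$prefilter_cycles / sqrt(log(2))
  H <- exp(-(g$fr^2) / s1^2)
  lowpass <- function(x) Re(ifft2(fft2(x) * H))
  u <- im - lowpass(im)
  env <- sqrt(pmax(lowpass(u^2), 0))
  u / (0.2 + env)
}

pool_grid <- function(mag, grid) {
  n <- nrow(mag)
  cuts <- ceiling(seq_len(n) / (n / grid))
  # average over grid x grid blocks, block index column-major
  out <- numeric(grid * grid)
  k <- 1L
  for (j in seq_len(grid)) {
    for (i in seq_len(grid)) {
      out[k] <- mean(mag[cuts == i, cuts == j])
      k <- k + 1L
    }
  }
  out
}

#' Extract a GIST descriptor from one image
#'
#' Applies the Gabor bank in the frequency domain to the preprocessed image;
#' each filter's energy magnitude image is average-pooled over a
#' `grid` x `grid` partition and the pooled blocks are concatenated
#' filter-major into the descriptor (length
#' `n_scales * n_orientations * grid^2`; 512 by default).
#'
#' @inheritParams preprocess_image
#' @param filters Optional precomputed [build_filter_bank()] output (reused
#'   across a batch).
#' @return Numeric descriptor vector, entries finite and nonnegative.
#' @examples
#' img <- matrix(runif(64 * 64), 64)
#' length(extract_gist(img)) # 512
#' @export
extract_gist <- function(image, config = gist_config(), filters = NULL) {
  stopifnot(inherits(config, "gist_config"))
  if (is.null(filters)) filters <- build_filter_bank(config)
  pre <- preprocess_image(image, config)
  Fim <- fft2(pre)
  desc <- unlist(lapply(filters, function(G) {
    pool_grid(Mod(ifft2(Fim * G)), config$grid)
  }), use.names = FALSE)
  if (config$normalize) {
    nrm <- sqrt(sum(desc^2))
    if (nrm > 0) desc <- desc / nrm
  }
  desc
}

#' Extract GIST descriptors for a batch of images
#'
#' @param images A nonempty list of intensity matrices (or color arrays), or a
#'   character vector of image file paths.
#' @param config A [gist_config()].
#' @param ids Identifiers (default: list names, file paths, or `img<i>`).
#' @param labels Optional integer labels per image.
#' @return A [feature_matrix()] whose column i is the descriptor of image i.
#' @export
extract_batch <- function(images, config = gist_config(), ids = NULL, labels = NULL) {
  if (is.character(images)) {
    if (is.null(ids)) ids <- images
    images <- lapply(images, read_image)
  }
  if (!is.list(images) || length(images) == 0) {
    srdml_stop("images must be a nonempty list or character vector of paths")
  }
  if (is.null(ids)) ids <- names(images) %||% sprintf("img%04d", seq_along(images))
  filters <- build_filter_bank(config)
  cols <- purrr::map2(images, seq_along(images), function(im, i) {
    tryCatch(
      extract_gist(im, config, filters = filters),
      error = function(e) srdml_stop("image '", ids[[i]], "': ", conditionMessage(e))
    )
  })
  X <- do.call(cbind, cols)
  colnames(X) <- ids
  feature_matrix(X, labels = labels, ids = ids)
}
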