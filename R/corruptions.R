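# Stimulus corruption operators: additive uniform pixel noise, Gaussian
# lowpass filtering with constant gray padding, grayscale conversion, and a
# 1/f pink-noise mask.  All operators map H x W x 3 arrays with values in
# [0, 1] to arrays of the same shape and range.

DEFAULT_BACKGROUND_GRAY <- 0.454

#' Validate an image array
#'
#' Images are `height x width x 3` numeric arrays of intensities in
#' \[0, 1\].  A `height x width` matrix is promoted to three equal channels.
#'
#' @param img candidate image.
#' @return The validated array.
#' @export
as_image <- function(img) {
  if (is.matrix(img)) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop("image must be a height x width x 3 array", call. = FALSE)
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 1) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  img
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Additive uniform pixel noise
#'
#' Adds, at every pixel location, a single uniform draw from
#' `[-half_width, half_width]` to all three channels (achromatic noise), then
#' clips the result to \[0, 1\].  Set `per_channel = TRUE` for three
#' independent draws per pixel instead.
#'
#' @param img image array (see [as_image()]).
#' @param half_width half width of the uniform noise interval; default 0.5
#'   corresponds to noise drawn from \[-0.5, 0.5\].
#' @param seed integer seed; the same seed reproduces the output bit for bit.
#' @param per_channel draw noise independently per channel.
#' @return Corrupted image, same shape, values in \[0, 1\].
#' @export
add_uniform_noise <- function(img, half_width = 0.5, seed = NULL,
                              per_channel = FALSE) {
  img <- as_image(img)
  stopifnot(half_width >= 0)
  if (half_width == 0) return(img)
  d <- dim(img)
  noise <- with_seed(seed, {
    if (per_channel) {
      array(stats::runif(prod(d), -half_width, half_width), dim = d)
    } else {
      field <- matrix(stats::runif(d[1L] * d[2L], -half_width, half_width),
                      d[1L], d[2L])
      array(rep(field, 3L), dim = d)
    }
  })
  clip01(img + noise)
}

# 1-D Gaussian kernel truncated at 4 sigma and renormalised.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# n x (n + 2r) band matrix whose i-th row holds the kernel aligned so that
# multiplying a padded signal of length n + 2r yields the valid convolution.
band_matrix <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  m <- matrix(0, n, n + 2L * r)
  for (i in seq_len(n)) m[i, i:(i + 2L * r)] <- k
  m
}

#' Gaussian lowpass filter with gray padding
#'
#' Convolves each channel with a 2-D Gaussian kernel (separable, truncated
#' at 4 sigma and renormalised), padding the image border with a constant
#' gray value, then clips to \[0, 1\].
#'
#' @param img image array.
#' @param sigma Gaussian standard deviation in pixels (> 0); default 5.0.
#' @param pad_value constant padding intensity; default 0.454, the
#'   experiment's background gray.
#' @return Filtered image, same shape, values in \[0, 1\].
#' @export
lowpass_filter <- function(img, sigma = 5.0, pad_value = DEFAULT_BACKGROUND_GRAY) {
  img <- as_image(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive number", call. = FALSE)
  }
  stopifnot(pad_value >= 0, pad_value <= 1)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  h <- dim(img)[1L]
  w <- dim(img)[2L]
  kh <- band_matrix(h, k)
  kw <- band_matrix(w, k)
  out <- img
  for (ch in 1:3) {
    padded <- matrix(pad_value, h + 2L * r, w + 2L * r)
    padded[(r + 1L):(r + h), (r + 1L):(r + w)] <- img[, , ch]
    out[, , ch] <- kh %*% padded %*% t(kw)
  }
  clip01(out)
}

#' Grayscale conversion
#'
#' Replaces each pixel by its luma, `0.299 R + 0.587 G + 0.114 B`,
#' replicated to all three channels.  Already-gray images are fixed points.
#'
#' @param img image array.
#' @return Grayscale image (all channels equal), same shape.
#' @export
to_grayscale <- function(img) {
  img <- as_image(img)
  w <- c(0.299, 0.587, 0.114)
  luma <- img[, , 1L] * w[1L] + img[, , 2L] * w[2L] + img[, , 3L] * w[3L]
  array(rep(luma, 3L), dim = dim(img))
}

#' Grayscale pink-noise mask
#'
#' Generates a grayscale field whose amplitude spectrum falls off as 1/f
#' with spatial frequency, by frequency-domain shaping of seeded white
#' noise: the Fourier transform of a Gaussian white-noise field is scaled by
#' 1/f (DC term zeroed), inverted, and the result min-max rescaled to
#' \[0, 1\] and replicated to three equal channels.
#'
#' @param height,width mask dimensions in pixels (>= 8).
#' @param seed integer seed.
#' @return `height x width x 3` array, channels equal, values in \[0, 1\].
#' @export
pink_noise_mask <- function(height, width, seed = NULL) {
  stopifnot(height >= 8L, width >= 8L)
  white <- with_seed(seed, matrix(stats::rnorm(height * width), height, width))
  fy <- fft_freq(height)
  fx <- fft_freq(width)
  f <- sqrt(outer(fy^2, fx^2, `+`))
  shape <- 1 / f
  shape[1L, 1L] <- 0  # zero DC; the overall level is set by the rescale
  field <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE))
  field <- (field - min(field)) / (max(field) - min(field))
  array(rep(field, 3L), dim = c(height, width, 3L))
}

# Discrete Fourier frequencies (cycles per sample) for length n.
fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

#' Radially averaged amplitude spectrum
#'
#' Bins the 2-D Fourier amplitude of a (grayscale) field by integer radial
#' frequency and returns the mean amplitude per ring, used to check spectral
#' slopes (pink noise has log-log slope about -1).
#'
#' @param field numeric matrix (one channel of an image).
#' @return Data frame with `freq` (cycles per image) and `amplitude`.
#' @export
radial_spectrum <- function(field) {
  stopifnot(is.matrix(field))
  n <- nrow(field)
  m <- ncol(field)
  amp <- Mod(stats::fft(field - mean(field)))
  fy <- fft_freq(n) * n
  fx <- fft_freq(m) * m
  r <- round(sqrt(outer(fy^2, fx^2, `+`)))
  keep <- r > 0 & r <= floor(min(n, m) / 2)
  means <- tapply(amp[keep], r[keep], mean)
  data.frame(freq = as.numeric(names(means)),
             amplitude = as.numeric(means))
}

#' Read and write images as PNG
#'
#' Thin wrappers around the `png` package.  Lossless 8-bit quantisation
#' happens only at I/O; operators always work on double arrays.
#'
#' @param path file path.
#' @return `read_image()` returns a validated image array.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3]  # drop alpha
  as_image(img)
}

#' @rdname read_image
#' @param img image array to write.
#' @export
write_image <- function(img, path) {
  img <- as_image(img)
  png::writePNG(img, target = path)
  invisible(path)
}
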