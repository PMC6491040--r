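#' Self-contained oriented filter-bank feature backend
#'
#' A differentiable feature extractor used for pooled-statistic synthesis
#' and local texture distortion. Features are halfwave-rectified responses
#' of a multi-scale bank of even-symmetric, zero-mean Gabor filters
#' (`n_scales` dyadic scales x `n_orient` orientations), plus one Gaussian
#' lowpass channel. Each scale is exposed as a "layer" (coarse analogue of
#' the ascending layers of a deep texture network), so Gram statistics can
#' be computed per layer. Convolution is circular (FFT-based); the same
#' kernels, fixed in pixels, are applied at every input size.
#'
#' The returned backend is a list with fields
#' \describe{
#'   \item{input_sizes}{sizes (px) the multiscale pooled representation
#'     uses (default 128, 256, 512).}
#'   \item{layer_channels}{integer vector, channels per layer.}
#'   \item{forward(x)}{features of a pixel matrix: list with `features`
#'     (H x W x C array, non-negative) and `pos` (rectifier gate pattern,
#'     needed by `vjp`).}
#'   \item{vjp(gbar, pos)}{vector-Jacobian product: gradient of any scalar
#'     objective w.r.t. pixels, given its gradient `gbar` w.r.t. the
#'     feature array and the gate pattern from the matching `forward`.}
#'   \item{differentiable}{TRUE.}
#' }
#'
#' @param input_sizes input sizes in px for multiscale pooling.
#' @param n_scales number of dyadic filter scales (default 4).
#' @param n_orient number of orientations (default 4).
#' @param base_sigma Gaussian envelope sd of the finest scale, px.
#' @return backend list as described above.
#' @export
filterbank_backend <- function(input_sizes = c(128, 256, 512),
                               n_scales = 4, n_orient = 4,
                               base_sigma = 1.5) {
  sigmas <- base_sigma * 2^(seq_len(n_scales) - 1)
  thetas <- pi * (seq_len(n_orient) - 1) / n_orient
  layer_channels <- c(rep(n_orient, n_scales), 1L)

  kernels <- list()
  for (s in seq_len(n_scales)) {
    for (th in thetas) kernels[[length(kernels) + 1L]] <-
      gabor_kernel(sigmas[s], th)
  }
  kernels[[length(kernels) + 1L]] <- gauss_kernel(sigmas[n_scales])

  fft_cache <- new.env(parent = emptyenv())
  kernel_ffts <- function(side) {
    key <- as.character(side)
    if (!is.null(fft_cache[[key]])) return(fft_cache[[key]])
    kf <- lapply(kernels, function(k) stats::fft(embed_kernel(k, side)))
    fft_cache[[key]] <- kf
    kf
  }

  forward <- function(x) {
    side <- nrow(x)
    kf <- kernel_ffts(side)
    xf <- stats::fft(x)
    C <- length(kf)
    lin <- array(0, c(side, side, C))
    for (c in seq_len(C))
      lin[, , c] <- Re(stats::fft(xf * kf[[c]], inverse = TRUE)) / side^2
    pos <- lin > 0
    lin[!pos] <- 0
    list(features = lin, pos = pos)
  }

  vjp <- function(gbar, pos) {
    side <- dim(gbar)[1]
    kf <- kernel_ffts(side)
    g <- matrix(0, side, side)
    acc <- matrix(0 + 0i, side, side)
    for (c in seq_len(dim(gbar)[3])) {
      gg <- gbar[, , c]
      gg[!pos[, , c]] <- 0
      acc <- acc + stats::fft(gg) * Conj(kf[[c]])
    }
    Re(stats::fft(acc, inverse = TRUE)) / side^2
  }

  structure(list(input_sizes = sort(input_sizes),
                 layer_channels = layer_channels,
                 n_channels = sum(layer_channels),
                 forward = forward, vjp = vjp,
                 differentiable = TRUE,
                 n_scales = n_scales, n_orient = n_orient,
                 sigmas = sigmas),
            class = "feature_backend")
}

#' @export
print.feature_backend <- function(x, ...) {
  cat(sprintf(
    "<feature_backend> %d layers, %d channels, input sizes %s\n",
    length(x$layer_channels), x$n_channels,
    paste(x$input_sizes, collapse = "/")))
  invisible(x)
}

# even (cosine-phase) Gabor, mean-subtracted within its Gaussian support
gabor_kernel <- function(sigma, theta, gamma = 0.8, lambda_ratio = 3) {
  half <- ceiling(3 * sigma)
  xs <- -half:half
  X <- outer(rep(1, length(xs)), xs)   # columns: x
  Y <- outer(xs, rep(1, length(xs)))   # rows: y
  xp <- X * cos(theta) + Y * sin(theta)
  yp <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-(xp^2 + (gamma * yp)^2) / (2 * sigma^2))
  k <- env * cos(2 * pi * xp / (lambda_ratio * sigma))
  k <- k - env * sum(k) / sum(env)     # zero DC response
  k / sqrt(sum(k^2))
}

gauss_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  xs <- -half:half
  g <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  g / sum(g)
}

# place kernel center at (1,1) with circular wrap, for phase-free FFT conv
embed_kernel <- function(k, side) {
  n <- nrow(k)
  if (n > side) stop("kernel larger than image", call. = FALSE)
  half <- (n - 1) / 2
  K <- matrix(0, side, side)
  idx <- (( -half:half ) %% side) + 1
  K[idx, idx] <- k
  K
}

# channel index ranges per layer
layer_slices <- function(layer_channels) {
  ends <- cumsum(layer_channels)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(function(a, b) a:b, starts, ends)
}
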