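#' Grayscale image container
#'
#' A `gray_image` is a square luminance raster in nominal range \[0, 1\]
#' together with its angular resolution in pixels per degree of visual
#' angle. It is the unit of all image operations in the package.
#'
#' @param pixels numeric matrix of luminance values.
#' @param px_per_deg pixels per degree of visual angle (default 40, the
#'   nominal resolution of the display the analysis assumes).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, px_per_deg = 40) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, px_per_deg = px_per_deg),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  p <- x$pixels
  cat(sprintf("<gray_image> %d x %d px, %.0f px/deg, mean %.4f, sd %.4f\n",
              nrow(p), ncol(p), x$px_per_deg, mean(p), stats::sd(p)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

as_pixel_matrix <- function(img) {
  if (inherits(img, "gray_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected a gray_image or a numeric matrix", call. = FALSE)
}

#' Prepare a raw raster for analysis
#'
#' Center-crops to a square, converts to grayscale by an unweighted channel
#' mean, and downsamples to `side` pixels using an area-averaging
#' (mean-preserving, antialiased) resampler.
#'
#' @param raw a numeric matrix (grayscale) or a 3-d numeric array
#'   (height x width x channels).
#' @param side output side length in pixels (default 512).
#' @param px_per_deg angular resolution assigned to the result.
#' @return A [gray_image()] of size `side` x `side`.
#' @export
prepare_image <- function(raw, side = 512, px_per_deg = 40) {
  if (is.array(raw) && length(dim(raw)) == 3) {
    raw <- apply(raw, c(1, 2), mean)          # unweighted channel mean
  }
  if (!is.matrix(raw))
    stop("`raw` must be a matrix or height x width x channel array",
         call. = FALSE)
  h <- nrow(raw); w <- ncol(raw)
  m <- min(h, w)
  if (m < side)
    stop(sprintf("input too small: min(height, width) = %d < side = %d",
                 m, side), call. = FALSE)
  r0 <- floor((h - m) / 2); c0 <- floor((w - m) / 2)
  sq <- raw[(r0 + 1):(r0 + m), (c0 + 1):(c0 + m), drop = FALSE]
  gray_image(resample_area(sq, side), px_per_deg = px_per_deg)
}

# Area-averaging resampler on a square raster. Each output pixel is the
# average of the input region it covers; fractional overlaps are weighted,
# so the global mean is preserved exactly.
resample_area <- function(x, side) {
  n <- nrow(x)
  if (n == side) return(x)
  W <- area_weights(n, side)     # side x n, rows sum to 1
  W %*% x %*% t(W)
}

area_weights <- function(n, side) {
  # overlap of output bin i ([(i-1)*n/side, i*n/side)) with input bin j
  W <- matrix(0, side, n)
  f <- n / side
  for (i in seq_len(side)) {
    lo <- (i - 1) * f; hi <- i * f
    j0 <- floor(lo) + 1; j1 <- ceiling(hi)
    for (j in j0:min(j1, n)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov
    }
    W[i, ] <- W[i, ] / f
  }
  W
}

#' Standardize an image to fixed luminance statistics
#'
#' Applies the affine map `x -> (x - mu)/sigma * (target_rms * target_mean)
#' + target_mean` so that the output has mean `target_mean` and RMS contrast
#' (sigma/mu) `target_rms` exactly. Pixels may leave \[0, 1\]; they are not
#' clipped (clipping would break the exact moment contract) — clipping
#' happens only at export, see [write_pgm()].
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param target_mean target mean gray value (default 0.5).
#' @param target_rms target RMS contrast sigma/mu (default 0.3).
#' @return A standardized [gray_image()].
#' @export
standardize <- function(img, target_mean = 0.5, target_rms = 0.3) {
  ppd <- if (inherits(img, "gray_image")) img$px_per_deg else 40
  x <- as_pixel_matrix(img)
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))   # population sd: exact moment contract
  if (sdev == 0)
    stop("constant image: cannot standardize (sd = 0)", call. = FALSE)
  y <- (x - mu) / sdev * (target_rms * target_mean) + target_mean
  gray_image(y, px_per_deg = ppd)
}

#' Read / write portable graymaps (PGM, plain text P2)
#'
#' `read_pgm` reads an ASCII ("P2") portable graymap into a [gray_image()]
#' scaled to \[0, 1\]. `write_pgm` maps \[0, 1\] onto the integer range
#' (clipping out-of-range pixels) and writes ASCII PGM; it returns the
#' fraction of pixels clipped, invisibly.
#'
#' @param path file path.
#' @param img a [gray_image()] or numeric matrix.
#' @param maxval integer white level (default 255; use 65535 for 16 bit).
#' @param px_per_deg resolution to attach on read.
#' @return `read_pgm`: a [gray_image()]. `write_pgm`: clipped fraction,
#'   invisibly.
#' @export
read_pgm <- function(path, px_per_deg = 40) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only plain (P2) PGM supported", call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: pixel count mismatch",
                                  call. = FALSE)
  gray_image(matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE),
             px_per_deg = px_per_deg)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  x <- as_pixel_matrix(img)
  clipped <- mean(x < 0 | x > 1)
  q <- round(pmin(pmax(x, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(x), nrow(x)), as.character(maxval)), con)
  write(t(q), file = con, ncolumns = min(ncol(x), 16L))
  invisible(clipped)
}
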