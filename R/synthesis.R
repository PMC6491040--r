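#' Pooled feature statistics of an image
#'
#' For each backend input size, the image is resampled (area averaging) to
#' that size, features are computed, and the spatial mean of every feature
#' channel is taken within every pooling region of that size's grid. The
#' result is the flat statistic vector that synthesis matches.
#'
#' @param img a [gray_image()] or numeric matrix; side must be a multiple
#'   of (and at least) every input size used.
#' @param grids a single [build_polar_grid()] (applied at its own side) or
#'   a list of grids whose sides cover `backend$input_sizes`.
#' @param backend a [filterbank_backend()].
#' @return An object of class `pooled_stats`: list with `values` (numeric
#'   vector) and `index` (data.frame with columns size, layer, channel,
#'   region).
#' @export
pool_statistics <- function(img, grids, backend) {
  x <- as_pixel_matrix(img)
  grids <- as_grid_list(grids)
  sizes <- as.integer(names(grids))
  if (nrow(x) < max(sizes))
    stop("image smaller than largest input size", call. = FALSE)
  vals <- list(); idx <- list()
  for (s in sizes) {
    g <- grids[[as.character(s)]]
    xr <- resample_area(x, s)
    fw <- backend$forward(xr)
    pooled <- region_means(fw$features, g)
    nr <- n_regions(g)
    lay <- rep(rep(seq_along(backend$layer_channels),
                   backend$layer_channels), each = nr)
    ch <- rep(seq_len(backend$n_channels), each = nr)
    vals[[length(vals) + 1L]] <- as.vector(pooled)
    idx[[length(idx) + 1L]] <- data.frame(
      size = s, layer = lay, channel = ch, region = rep(seq_len(nr),
                                                        backend$n_channels))
  }
  structure(list(values = unlist(vals), index = do.call(rbind, idx)),
            class = "pooled_stats")
}

as_grid_list <- function(grids) {
  if (inherits(grids, "pooling_grid")) grids <- list(grids)
  out <- list()
  for (g in grids) out[[as.character(g$side)]] <- g
  out
}

# matrix of region means: n_regions x n_channels
region_means <- function(features, grid) {
  lab <- as.vector(grid$labels)
  keep <- lab > 0
  labk <- lab[keep]
  cnt <- tabulate(labk, nbins = n_regions(grid))
  C <- dim(features)[3]
  fm <- matrix(features, ncol = C)[keep, , drop = FALSE]
  rowsum(fm, labk, reorder = TRUE) / cnt
}

#' Normalized mean squared error between statistic matrices
#'
#' `mean((orig - synth)^2) / Var(orig)`, the synthesis-quality metric, with
#' `Var` the population variance of the reference statistics.
#'
#' @param stats_orig,stats_synth numeric vectors/matrices of equal shape
#'   (or `pooled_stats` objects).
#' @return non-negative scalar.
#' @export
normalized_mse <- function(stats_orig, stats_synth) {
  a <- if (inherits(stats_orig, "pooled_stats")) stats_orig$values
       else as.numeric(stats_orig)
  b <- if (inherits(stats_synth, "pooled_stats")) stats_synth$values
       else as.numeric(stats_synth)
  if (length(a) != length(b))
    stop("statistic containers differ in shape", call. = FALSE)
  v <- mean((a - mean(a))^2)
  if (v == 0) stop("zero-variance reference statistics", call. = FALSE)
  mean((a - b)^2) / v
}

#' Synthesize an image matching pooled feature statistics
#'
#' Starting from Gaussian noise (with the original's mean and sd) outside a
#' pinned central disk, minimizes the mean squared difference between the
#' image's pooled statistics and `target` by gradient descent
#' (Barzilai-Borwein step length with Armijo backtracking, so the loss is
#' non-increasing over accepted steps). Pixels within `pinned_radius` of
#' the image center are held at the original's values throughout.
#'
#' @param target a `pooled_stats` from [pool_statistics()] with the same
#'   grids and backend.
#' @param original the reference [gray_image()] (supplies the pinned disk
#'   and the noise moments).
#' @param grids,backend as in [pool_statistics()].
#' @param n_steps maximum number of gradient steps (default 1000).
#' @param pinned_radius radius (px, at full resolution) of the protected
#'   central disk (default 64).
#' @param seed RNG seed for the noise initialization.
#' @param init optional full starting image (overrides noise; the pinned
#'   disk is still reset to the original).
#' @param pin if FALSE the central disk is only initialized, not held.
#' @param tol stop when the relative loss decrease falls below this.
#' @return A [gray_image()] with attributes `loss` (per accepted step,
#'   element 1 = initial loss) and `final_loss`.
#' @export
synthesize_pooled <- function(target, original, grids, backend,
                              n_steps = 1000, pinned_radius = 64,
                              seed = 1, init = NULL, pin = TRUE,
                              tol = 1e-9) {
  if (!isTRUE(backend$differentiable))
    stop("backend does not support gradients", call. = FALSE)
  x0 <- as_pixel_matrix(original)
  side <- nrow(x0)
  grids <- as_grid_list(grids)
  ctr <- (side - 1) / 2
  cc <- seq_len(side) - 1
  dist <- sqrt(outer((cc - ctr)^2, (cc - ctr)^2, "+"))
  pinned <- dist <= pinned_radius
  if (is.null(init)) {
    set.seed(seed)
    x <- matrix(stats::rnorm(side^2, mean(x0), stats::sd(x0)), side, side)
  } else x <- as_pixel_matrix(init)
  x[pinned] <- x0[pinned]
  free <- if (pin) !pinned else matrix(TRUE, side, side)

  obj <- function(x) pooled_loss_grad(x, target, grids, backend)
  descend(x, free, obj, n_steps, tol)
}

# loss = sum over sizes of mean((pooled - target)^2); gradient chained
# through region pooling, rectification, convolution and area resampling
pooled_loss_grad <- function(x, target, grids, backend) {
  side <- nrow(x)
  loss <- 0
  grad <- matrix(0, side, side)
  for (s in as.integer(names(grids))) {
    g <- grids[[as.character(s)]]
    xr <- resample_area(x, s)
    fw <- backend$forward(xr)
    pooled <- region_means(fw$features, g)
    tv <- target$values[target$index$size == s]
    dif <- pooled - matrix(tv, nrow = n_regions(g))
    nstat <- length(dif)
    loss <- loss + mean(dif^2)
    # gradient w.r.t. each feature map pixel: (2/nstat) * dif / count
    lab <- as.vector(g$labels)
    cnt <- tabulate(lab[lab > 0], nbins = n_regions(g))
    scale <- dif * (2 / nstat) / cnt           # n_regions x C
    C <- dim(fw$features)[3]
    gbar <- array(0, dim(fw$features))
    look <- rbind(0, scale)                    # row 1 for label 0
    for (c in seq_len(C))
      gbar[, , c] <- matrix(look[lab + 1L, c], s, s)
    gr <- backend$vjp(gbar, fw$pos)
    if (s == side) grad <- grad + gr
    else {
      W <- area_weights(side, s)
      grad <- grad + t(W) %*% gr %*% W
    }
  }
  list(loss = loss, grad = grad)
}

# monotone BB-with-backtracking descent over the free pixels
descend <- function(x, free, obj, n_steps, tol) {
  ev <- obj(x)
  losses <- ev$loss
  g <- ev$grad; g[!free] <- 0
  step <- 1 / max(sqrt(sum(g^2)), 1e-12)
  x_prev <- NULL; g_prev <- NULL
  for (it in seq_len(n_steps)) {
    if (sqrt(sum(g^2)) < 1e-14) break
    if (!is.null(x_prev)) {
      sv <- x - x_prev; yv <- g - g_prev
      sy <- sum(sv * yv)
      step <- if (sy > 0) sum(sv * sv) / sy else step * 2
    }
    accepted <- FALSE
    for (bt in 1:30) {
      xn <- x - step * g
      evn <- obj(xn)
      if (evn$loss <= ev$loss - 1e-4 * step * sum(g^2)) {
        accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) break
    x_prev <- x; g_prev <- g
    x <- xn
    rel <- (ev$loss - evn$loss) / max(ev$loss, 1e-300)
    ev <- evn
    g <- ev$grad; g[!free] <- 0
    losses <- c(losses, ev$loss)
    if (rel < tol) break
  }
  out <- gray_image(x)
  attr(out, "loss") <- losses
  attr(out, "final_loss") <- ev$loss
  out
}

#' Per-layer Gram matrices of feature maps
#'
#' For each backend layer, the channel-by-channel inner-product matrix of
#' the feature maps over the whole patch, divided by the patch pixel count.
#' A stationary texture descriptor: it discards the spatial arrangement of
#' features within the patch.
#'
#' @param img patch as [gray_image()] or matrix.
#' @param backend a [filterbank_backend()].
#' @return list of symmetric positive semidefinite matrices, one per layer.
#' @export
gram_stats <- function(img, backend) {
  x <- as_pixel_matrix(img)
  fw <- backend$forward(x)
  grams_from_features(fw$features, backend)
}

grams_from_features <- function(features, backend) {
  n <- prod(dim(features)[1:2])
  fm <- matrix(features, ncol = dim(features)[3])
  lapply(layer_slices(backend$layer_channels), function(sl)
    crossprod(fm[, sl, drop = FALSE]) / n)
}

#' Insert a localized texture distortion into an image
#'
#' Replaces a circular region with a texture-matched resynthesis: the Gram
#' matrices of a square patch of side `2 * (radius + margin)` centered on
#' `center` are matched by gradient descent, and the result is blended into
#' the original through a circular raised-cosine window that ramps from 1
#' to 0 over the `ramp` px just inside the circle of `radius`. Pixels at
#' distance >= `radius` from `center` are bitwise unchanged.
#'
#' @param img a [gray_image()].
#' @param center distortion center, `c(x, y)` in 0-based px.
#' @param radius distortion radius in px (the experiment used 40, 70, 85
#'   and 100 px).
#' @param backend a [filterbank_backend()].
#' @param ramp blending ramp width in px (default 12).
#' @param margin extra statistics support beyond `radius` (default 24; the
#'   statistics window side is `2 * (radius + margin)`).
#' @param n_steps gradient steps for the texture match (default 300).
#' @param seed RNG seed for the noise initialization.
#' @return A [gray_image()] with attribute `loss` (Gram-matching loss per
#'   accepted step).
#' @export
make_local_distortion <- function(img, center, radius, backend,
                                  ramp = 12, margin = 24, n_steps = 300,
                                  seed = 1) {
  x <- as_pixel_matrix(img)
  side <- nrow(x)
  half <- radius + margin
  cx <- center[1]; cy <- center[2]
  x0 <- round(cx) - half; y0 <- round(cy) - half   # top-left, 0-based
  L <- 2 * half
  if (x0 < 0 || y0 < 0 || x0 + L > side || y0 + L > side)
    stop("distortion patch exceeds image bounds", call. = FALSE)
  rows <- (y0 + 1):(y0 + L); cols <- (x0 + 1):(x0 + L)
  patch <- x[rows, cols]
  gt <- gram_stats(patch, backend)

  obj <- function(p) gram_loss_grad(p, gt, backend)
  set.seed(seed)
  p0 <- matrix(stats::rnorm(L^2, mean(patch), stats::sd(patch)), L, L)
  synth <- descend(p0, matrix(TRUE, L, L), obj, n_steps, 1e-9)

  # raised-cosine blend in the full image frame
  xs <- seq_len(side) - 1
  dist <- sqrt(outer((xs - cy)^2, (xs - cx)^2, "+"))  # rows y, cols x
  w <- blend_weight(dist, radius, ramp)
  full <- x
  full[rows, cols] <- as_pixel_matrix(synth)
  out <- w * full + (1 - w) * x
  res <- gray_image(out, px_per_deg = if (inherits(img, "gray_image"))
    img$px_per_deg else 40)
  attr(res, "loss") <- attr(synth, "loss")
  res
}

# 1 inside radius - ramp, 0 outside radius, half-cosine between
blend_weight <- function(dist, radius, ramp) {
  w <- matrix(0, nrow(dist), ncol(dist))
  w[dist <= radius - ramp] <- 1
  mid <- dist > radius - ramp & dist < radius
  w[mid] <- 0.5 * (1 + cos(pi * (dist[mid] - (radius - ramp)) / ramp))
  w
}

gram_loss_grad <- function(p, gt, backend) {
  fw <- backend$forward(p)
  n <- prod(dim(p))
  fm <- matrix(fw$features, ncol = dim(fw$features)[3])
  sl <- layer_slices(backend$layer_channels)
  loss <- 0
  gfm <- matrix(0, nrow(fm), ncol(fm))
  for (l in seq_along(sl)) {
    Fl <- fm[, sl[[l]], drop = FALSE]
    G <- crossprod(Fl) / n
    D <- G - gt[[l]]
    C <- length(sl[[l]])
    loss <- loss + mean(D^2)
    gfm[, sl[[l]]] <- Fl %*% (D * (4 / (C^2 * n)))   # d mean(D^2) / dF
  }
  gbar <- array(gfm, dim(fw$features))
  list(loss = loss, grad = backend$vjp(gbar, fw$pos))
}
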