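#' Eccentricity-scaled polar pooling grid
#'
#' Partitions the annulus between `inner_radius` and the image corner into
#' `n_angular` x `n_radial` hard (binary, non-overlapping) regions. Angular
#' bins are uniform in angle starting at the positive x-axis,
#' counterclockwise. Radial bin edges are geometrically spaced by default,
#' which makes the pooling-region scale factor (radial extent divided by
#' eccentricity) constant across rings — the defining property of an
#' eccentricity-scaled pooling model; linear spacing is available behind
#' `spacing` for comparison.
#'
#' Pixel centers sit at integer 0-based coordinates; fixation is at
#' `((side-1)/2, (side-1)/2)`; a pixel's eccentricity is the Euclidean
#' distance of its center from fixation. Pixels inside `inner_radius` form
#' a protected foveal region excluded from pooling (label 0), as are the
#' corner pixels beyond `outer_radius`.
#'
#' @param side image side length in pixels.
#' @param n_angular number of angular bins (default 32).
#' @param n_radial number of radial bins (default 28).
#' @param inner_radius foveal exclusion radius in pixels (default 64).
#' @param spacing `"geometric"` (default) or `"linear"` radial bin edges.
#' @return An object of class `pooling_grid` with fields `labels` (integer
#'   raster, 0 for unpooled pixels, else region id in `1:(n_angular *
#'   n_radial)`), `radial_edges`, `n_angular`, `n_radial`, `center`,
#'   `region_eccentricity` and `region_diameter` (per-region, in px).
#' @export
build_polar_grid <- function(side, n_angular = 32, n_radial = 28,
                             inner_radius = 64, spacing = c("geometric",
                                                            "linear")) {
  spacing <- match.arg(spacing)
  if (n_angular < 1 || n_radial < 1)
    stop("n_angular and n_radial must be >= 1", call. = FALSE)
  outer_radius <- side / 2 * sqrt(2)
  if (inner_radius >= outer_radius || side <= 2 * inner_radius)
    stop("inner_radius too large for this image side", call. = FALSE)
  edges <- switch(spacing,
    geometric = exp(seq(log(inner_radius), log(outer_radius),
                        length.out = n_radial + 1)),
    linear    = seq(inner_radius, outer_radius, length.out = n_radial + 1))
  ctr <- (side - 1) / 2
  xs <- seq_len(side) - 1
  ecc <- sqrt(outer(xs - ctr, xs - ctr, function(a, b) a^2 + b^2))
  # rows index y, cols index x; angle measured ccw from +x axis
  ang <- atan2(outer(xs - ctr, rep(1, side)), outer(rep(1, side), xs - ctr))
  ang <- (ang + 2 * pi) %% (2 * pi)
  rbin <- findInterval(ecc, edges, rightmost.closed = TRUE)
  rbin[rbin < 1 | rbin > n_radial | ecc < inner_radius] <- NA
  abin <- pmin(floor(ang / (2 * pi / n_angular)), n_angular - 1)
  lab <- (rbin - 1L) * n_angular + abin + 1L
  lab[is.na(lab)] <- 0L
  storage.mode(lab) <- "integer"
  mid <- (edges[-1] + edges[-(n_radial + 1)]) / 2  # ring mid eccentricity
  structure(list(
    labels = lab, side = side, n_angular = n_angular, n_radial = n_radial,
    inner_radius = inner_radius, outer_radius = outer_radius,
    radial_edges = edges, spacing = spacing, center = c(ctr, ctr),
    region_eccentricity = rep(mid, each = n_angular),
    region_diameter = rep(diff(edges), each = n_angular)),
    class = "pooling_grid")
}

#' @export
print.pooling_grid <- function(x, ...) {
  cat(sprintf(
    "<pooling_grid> %d px, %d angular x %d radial = %d regions, r in [%g, %.1f], %s spacing\n",
    x$side, x$n_angular, x$n_radial, x$n_angular * x$n_radial,
    x$inner_radius, x$outer_radius, x$spacing))
  invisible(x)
}

#' Number of regions in a pooling grid
#' @param grid a [build_polar_grid()] result.
#' @export
n_regions <- function(grid) grid$n_angular * grid$n_radial

#' Binary mask of one pooling region
#' @param grid a [build_polar_grid()] result.
#' @param i region id in `1:n_regions(grid)`.
#' @return logical matrix of the region's pixels.
#' @export
grid_mask <- function(grid, i) grid$labels == i

#' Scale factor of a pooling grid
#'
#' The scale factor is the ratio of pooling-region (radial) diameter to
#' eccentricity. With geometric radial spacing of ratio `rho` between
#' consecutive edges this is `2 (rho - 1) / (rho + 1)` for every ring (the
#' diameter is `e (rho - 1)` and the arithmetic mid-eccentricity
#' `e (rho + 1) / 2`); with other spacings it varies by ring.
#'
#' @param grid a [build_polar_grid()] result.
#' @return list with `per_region` (diameter / arithmetic mid eccentricity,
#'   one value per region) and `s` (their mean, the grid's nominal scale
#'   factor).
#' @export
grid_scale_factor <- function(grid) {
  e <- grid$radial_edges
  mid <- (e[-1] + e[-length(e)]) / 2
  per_ring <- diff(e) / mid
  per_region <- rep(per_ring, each = grid$n_angular)
  list(per_region = per_region, s = mean(per_ring))
}

#' Serialize / restore a pooling grid descriptor
#'
#' The JSON descriptor stores the construction parameters (not the label
#' raster); `read_grid_json` rebuilds the identical grid.
#'
#' @param grid a [build_polar_grid()] result.
#' @param path file path for the JSON descriptor.
#' @export
write_grid_json <- function(grid, path) {
  jsonlite::write_json(
    list(side = grid$side, n_angular = grid$n_angular,
         n_radial = grid$n_radial, inner_radius = grid$inner_radius,
         spacing = grid$spacing, radial_edges = grid$radial_edges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_grid_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_polar_grid(d$side, d$n_angular, d$n_radial, d$inner_radius,
                   spacing = d$spacing)
}
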