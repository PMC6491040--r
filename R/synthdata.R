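#' Ground-truth generating parameters for simulated oddity data
#'
#' Defaults mirror the regime the analysis is designed for: population
#' critical scales of 0.22 (scene) / 0.36 (texture) when originals are
#' compared against syntheses and 0.28 / 0.37 when two syntheses are
#' compared; gains of 2.7 d-prime units in the orig-vs-synth comparison
#' and 1.6 in synth-vs-synth (asymptotic performance is poorer when both
#' stimuli are distorted); modest participant (0.10) and image (0.15)
#' heterogeneity on the log scale; and the standard design of 8
#' participants, 10 scene + 10 texture images, 8 scale factors and 4
#' trials per cell.
#'
#' @param s_c named numeric: true critical scale per condition cell
#'   (names `<comparison>.<image_type>`).
#' @param alpha named numeric: true gain per condition cell.
#' @param participant_sd,image_sd random-effect sds on the log scale
#'   (applied to both log critical scale and log gain).
#' @param n_participants,n_images_per_type,scales,trials_per_cell design.
#' @param comparisons which comparison conditions to simulate.
#' @param seed RNG seed.
#' @return object of class `generating_params`.
#' @export
generating_params <- function(
    s_c = c(orig_vs_synth.scene = 0.22, orig_vs_synth.texture = 0.36,
            synth_vs_synth.scene = 0.28, synth_vs_synth.texture = 0.37),
    alpha = c(orig_vs_synth.scene = 2.7, orig_vs_synth.texture = 2.7,
              synth_vs_synth.scene = 1.6, synth_vs_synth.texture = 1.6),
    participant_sd = 0.10, image_sd = 0.15, n_participants = 8,
    n_images_per_type = 10,
    scales = c(0.25, 0.36, 0.46, 0.59, 0.7, 0.86, 1.09, 1.45),
    trials_per_cell = 4,
    comparisons = c("orig_vs_synth", "synth_vs_synth"), seed = 1) {
  stopifnot(participant_sd >= 0, image_sd >= 0, all(scales > 0),
            n_participants >= 1, n_images_per_type >= 1,
            trials_per_cell >= 1, all(s_c > 0), all(alpha > 0))
  structure(list(s_c = s_c, alpha = alpha, participant_sd = participant_sd,
                 image_sd = image_sd, n_participants = n_participants,
                 n_images_per_type = n_images_per_type, scales = scales,
                 trials_per_cell = trials_per_cell,
                 comparisons = comparisons, seed = seed),
            class = "generating_params")
}

#' Simulate an oddity trial table from known ground truth
#'
#' The generative mirror of [fit_critical_scale()]: participant offsets
#' (per participant x condition cell) and image offsets (per image x
#' comparison) are drawn from centered normals on the log scale, each
#' cell's success probability is
#' `weibull_pc(dprime_of_scale(s; s_c, alpha))`, and correct counts are
#' binomial. Deterministic given `gp$seed`.
#'
#' @param gp a [generating_params()] object.
#' @param link a `link_params` with `m = 3`.
#' @return A data.frame trial table (columns participant, image,
#'   image_type, comparison, model, scale, n_trials, n_correct) with the
#'   ground truth attached as attribute `truth`.
#' @export
gen_trials <- function(gp, link) {
  stopifnot(inherits(gp, "generating_params"), link$m == 3)
  set.seed(gp$seed)
  parts <- sprintf("p%02d", seq_len(gp$n_participants))
  imgs <- c(sprintf("scene%02d", seq_len(gp$n_images_per_type)),
            sprintf("texture%02d", seq_len(gp$n_images_per_type)))
  types <- rep(c("scene", "texture"), each = gp$n_images_per_type)

  cells <- expand.grid(comparison = gp$comparisons,
                       image_type = c("scene", "texture"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cellkey <- paste(cells$comparison, cells$image_type, sep = ".")

  p_off_sc <- matrix(stats::rnorm(length(parts) * nrow(cells), 0,
                                  gp$participant_sd),
                     length(parts), dimnames = list(parts, cellkey))
  p_off_a <- matrix(stats::rnorm(length(parts) * nrow(cells), 0,
                                 gp$participant_sd),
                    length(parts), dimnames = list(parts, cellkey))
  i_off_sc <- matrix(stats::rnorm(length(imgs) * length(gp$comparisons), 0,
                                  gp$image_sd),
                     length(imgs), dimnames = list(imgs, gp$comparisons))
  i_off_a <- matrix(stats::rnorm(length(imgs) * length(gp$comparisons), 0,
                                 gp$image_sd),
                    length(imgs), dimnames = list(imgs, gp$comparisons))

  tab <- expand.grid(participant = parts, image = imgs,
                     comparison = gp$comparisons, scale = gp$scales,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$image_type <- types[match(tab$image, imgs)]
  key <- paste(tab$comparison, tab$image_type, sep = ".")
  lsc <- log(gp$s_c[key]) +
    p_off_sc[cbind(tab$participant, key)] +
    i_off_sc[cbind(tab$image, tab$comparison)]
  la <- log(gp$alpha[key]) +
    p_off_a[cbind(tab$participant, key)] +
    i_off_a[cbind(tab$image, tab$comparison)]
  dp <- dprime_of_scale(tab$scale, exp(lsc), exp(la))
  p <- weibull_pc(dp, link)
  tab$model <- "FS"
  tab$n_trials <- gp$trials_per_cell
  tab$n_correct <- stats::rbinom(nrow(tab), tab$n_trials, p)
  tab <- tab[, c("participant", "image", "image_type", "comparison",
                 "model", "scale", "n_trials", "n_correct")]
  attr(tab, "truth") <- list(gp = gp, p_off_sc = p_off_sc,
                             p_off_a = p_off_a, i_off_sc = i_off_sc,
                             i_off_a = i_off_a, p = p)
  tab
}

#' Generate a procedural test image
#'
#' `texture_like` images are stationary filtered noise (spatially
#' homogeneous statistics, the regime in which summary-statistic pooling
#' models do well). `scene_like` images are compositions of sharp-edged
#' polygons, long bars and explicit T- and L-junctions clustered around a
#' random focus, giving spatially inhomogeneous structure with long
#' contours. Both are standardized to mean 0.5 and RMS contrast 0.3 and
#' are bit-reproducible given `(side, kind, seed)`.
#'
#' @param side image side in px (>= 64).
#' @param kind `"texture_like"` or `"scene_like"`.
#' @param seed RNG seed.
#' @return a standardized [gray_image()].
#' @export
gen_image <- function(side, kind = c("texture_like", "scene_like"),
                      seed = 1) {
  kind <- match.arg(kind)
  stopifnot(side >= 64)
  set.seed(seed)
  x <- if (kind == "texture_like") texture_noise(side)
       else scene_composition(side)
  standardize(gray_image(x))
}

# stationary 1/f-filtered noise with mild orientation bias
texture_noise <- function(side) {
  z <- matrix(stats::rnorm(side^2), side, side)
  f <- stats::fft(z)
  fr <- c(0:(side %/% 2), -((side - side %/% 2 - 1):1)) / side
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  rad[1, 1] <- Inf                       # kill DC
  amp <- 1 / (rad + 0.02)
  Re(stats::fft(f * amp, inverse = TRUE)) / side^2
}

# polygons, bars and junction primitives clustered around a focus point
scene_composition <- function(side) {
  x <- matrix(0.5, side, side)
  xs <- seq_len(side) - 1
  focus <- stats::runif(2, 0.2 * side, 0.5 * side)
  draw_rect <- function(x, cx, cy, w, h, ang, val) {
    dx <- outer(rep(1, side), xs - cx); dy <- outer(xs - cy, rep(1, side))
    u <- dx * cos(ang) + dy * sin(ang)
    v <- -dx * sin(ang) + dy * cos(ang)
    x[abs(u) <= w / 2 & abs(v) <= h / 2] <- val
    x
  }
  for (i in 1:6) {    # polygonal blobs near the focus
    c0 <- focus + stats::rnorm(2, 0, side / 8)
    x <- draw_rect(x, c0[1], c0[2], stats::runif(1, side / 10, side / 4),
                   stats::runif(1, side / 10, side / 4),
                   stats::runif(1, 0, pi), stats::runif(1))
  }
  for (i in 1:3) {    # long bars (extended contours)
    c0 <- focus + stats::rnorm(2, 0, side / 6)
    x <- draw_rect(x, c0[1], c0[2], stats::runif(1, 0.6, 0.95) * side,
                   stats::runif(1, 2, 5), stats::runif(1, 0, pi),
                   stats::runif(1))
  }
  for (i in 1:4) {    # T- and L-junctions: two perpendicular bars meeting
    c0 <- focus + stats::rnorm(2, 0, side / 6)
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, side / 8, side / 4)
    val <- stats::runif(1)
    tee <- stats::runif(1) < 0.5
    off <- if (tee) 0 else len / 2      # T joins mid-bar, L joins at end
    x <- draw_rect(x, c0[1], c0[2], len, 3, ang, val)
    x <- draw_rect(x, c0[1] + cos(ang + pi / 2) * len / 2,
                   c0[2] + sin(ang + pi / 2) * len / 2 + off, len, 3,
                   ang + pi / 2, val)
  }
  x
}
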