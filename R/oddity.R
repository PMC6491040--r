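#' Sensitivity as a function of pooling scale factor
#'
#' The two-parameter critical-scale function: `d'(s) = 0` for `s <= s_c`
#' and `alpha * (1 - s_c^2 / s^2)` above it. `s_c` is the critical scale
#' (largest scale factor at which synthesized and reference stimuli remain
#' indiscriminable) and `alpha` the asymptotic sensitivity in d-prime
#' units. The function is continuous at `s = s_c` and saturates at `alpha`
#' as `s` grows.
#'
#' @param s scale factor(s), > 0.
#' @param s_c critical scale, > 0.
#' @param alpha gain (asymptotic d-prime), > 0.
#' @return d-prime value(s), >= 0.
#' @export
dprime_of_scale <- function(s, s_c, alpha) {
  stopifnot(all(s > 0), all(s_c > 0), all(alpha > 0))
  ifelse(s > s_c, alpha * (1 - s_c^2 / s^2), 0)
}

#' Weibull link from d-prime to proportion correct
#'
#' `p = 1/m + (1 - 1/m) * (1 - exp(-(d'/lambda)^k))`: guess rate `1/m`,
#' increasing in d-prime, approaching 1. The scale `lambda` and shape `k`
#' are calibrated against a Monte-Carlo oddity observer by
#' [calibrate_link()]; they are not free parameters of the psychometric
#' model.
#'
#' @param dprime sensitivity value(s), >= 0.
#' @param link a `link_params` object from [link_params()] or
#'   [calibrate_link()].
#' @return proportion(s) correct in `[1/m, 1)`.
#' @export
weibull_pc <- function(dprime, link) {
  stopifnot(all(dprime >= 0))
  1 / link$m + (1 - 1 / link$m) * (1 - exp(-(dprime / link$lam)^link$k))
}

#' Link parameter container
#'
#' @param lam Weibull scale, > 0.
#' @param k Weibull shape, > 0.
#' @param m number of alternatives (default 3).
#' @return object of class `link_params`.
#' @export
link_params <- function(lam, k, m = 3L) {
  stopifnot(lam > 0, k > 0, m >= 2)
  structure(list(lam = lam, k = k, m = as.integer(m)),
            class = "link_params")
}

#' @export
print.link_params <- function(x, ...) {
  cat(sprintf("<link_params> m = %d, lambda = %.4f, k = %.4f\n",
              x$m, x$lam, x$k))
  invisible(x)
}

#' Monte-Carlo oddity observer
#'
#' Simulates the unbiased ideal observer for the three-stimulus oddity
#' task: each triad consists of two draws from a standard normal source
#' and one from a source shifted by `dprime`; the observer picks the
#' observation farthest from the mean of the other two (ties, which have
#' probability zero for continuous draws, are broken uniformly).
#'
#' @param dprime sensitivity, >= 0.
#' @param n_triads number of simulated triads.
#' @param seed RNG seed.
#' @param rule decision rule; only `"farthest_from_mean"` is built in, the
#'   argument exists so alternative observers can be swapped in.
#' @return proportion of triads answered correctly.
#' @export
simulate_oddity_pc <- function(dprime, n_triads, seed = 1,
                               rule = "farthest_from_mean") {
  stopifnot(dprime >= 0, n_triads >= 1)
  if (!identical(rule, "farthest_from_mean"))
    stop("unknown oddity decision rule: ", rule, call. = FALSE)
  set.seed(seed)
  x <- matrix(stats::rnorm(3 * n_triads), ncol = 3)
  odd <- sample.int(3, n_triads, replace = TRUE)
  x[cbind(seq_len(n_triads), odd)] <-
    x[cbind(seq_len(n_triads), odd)] + dprime
  d1 <- abs(x[, 1] - (x[, 2] + x[, 3]) / 2)
  d2 <- abs(x[, 2] - (x[, 1] + x[, 3]) / 2)
  d3 <- abs(x[, 3] - (x[, 1] + x[, 2]) / 2)
  D <- cbind(d1, d2, d3)
  pick <- max.col(D, ties.method = "random")
  mean(pick == odd)
}

#' Calibrate the Weibull link against the oddity observer
#'
#' Simulates the oddity observer's proportion correct on a grid of d-prime
#' values and chooses the Weibull scale and shape minimizing the summed
#' squared difference between the Weibull link and the simulated values.
#' Deterministic given `seed`.
#'
#' @param m number of alternatives (default 3).
#' @param dprime_grid grid of d-prime values (default 0 to 6 by 0.25; must
#'   reach at least 4 to constrain the saturation).
#' @param n_triads triads per grid point (default 1e5).
#' @param seed RNG seed.
#' @param simulator function `(dprime, n_triads, seed) -> pc` producing the
#'   calibration data (default [simulate_oddity_pc()]; swappable for
#'   closed-loop self-tests or alternative observers).
#' @return a `link_params` object with attributes `rss` (residual sum of
#'   squares), `grid` and `pc_sim` (the calibration data).
#' @export
calibrate_link <- function(m = 3L, dprime_grid = seq(0, 6, by = 0.25),
                           n_triads = 1e5, seed = 1,
                           simulator = simulate_oddity_pc) {
  stopifnot(max(dprime_grid) >= 4)
  pc <- vapply(seq_along(dprime_grid), function(i)
    simulator(dprime_grid[i], n_triads, seed = seed + i),
    numeric(1))
  sse <- function(par) {
    l <- link_params(exp(par[1]), exp(par[2]), m)
    sum((weibull_pc(dprime_grid, l) - pc)^2)
  }
  fit <- stats::optim(c(log(1.5), log(1.5)), sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("link calibration failed to converge (code ", fit$convergence,
         ")", call. = FALSE)
  out <- link_params(exp(fit$par[1]), exp(fit$par[2]), m)
  attr(out, "rss") <- fit$value
  attr(out, "grid") <- dprime_grid
  attr(out, "pc_sim") <- pc
  out
}

#' Serialize link parameters to/from JSON
#' @param link a `link_params` object.
#' @param path file path.
#' @export
write_link_json <- function(link, path) {
  jsonlite::write_json(list(m = link$m, lam = link$lam, k = link$k),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_link_json
#' @export
read_link_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  link_params(d$lam, d$k, d$m)
}
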