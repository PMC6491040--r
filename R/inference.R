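#' Fit the hierarchical critical-scale model
#'
#' Bayesian nonlinear mixed-effects estimation of critical scale and gain
#' from binomial oddity data. The likelihood for each cell is binomial
#' with success probability `weibull_pc(dprime_of_scale(s; s_c, alpha))`,
#' where `log s_c` and `log alpha` are each modeled as a population
#' intercept plus fixed effects of image type and comparison (with
#' interaction, so every condition cell has its own level), plus a
#' participant offset (participants crossed with comparison and image
#' type) and an image offset (images crossed with comparison, nested
#' within image type). Random effects are non-centered; group standard
#' deviations get half-Cauchy(0, 0.1) priors; the `log s_c` intercept
#' prior is Normal(-0.69, 1) (centered on a critical scale of about 0.5),
#' the `log alpha` intercept prior Normal(1, 1), and all other fixed
#' effects Normal(0, 0.5). Sampling is by an adaptive
#' Metropolis-within-Gibbs chain written in C++; convergence is assessed
#' with the split-chain Rhat statistic.
#'
#' Rows with `model != "FS"` carry no scale covariate (their abscissa is
#' arbitrary) and are dropped from the fit with a message; use
#' [pc_by_condition()] for their descriptive statistics.
#'
#' @param trials a trial table (see [gen_trials()] / [filter_trials()]):
#'   data.frame with columns participant, image, image_type
#'   (scene/texture), comparison (orig_vs_synth/synth_vs_synth), model,
#'   scale, n_trials, n_correct.
#' @param link a `link_params` object (fixed during fitting, as in the
#'   two-stage procedure: calibrate the link once, then fit).
#' @param chains,iter,warmup MCMC settings. Defaults are the full
#'   4 x 20000 (10000 warmup) regime; reduce for desk-scale work.
#' @param seed RNG seed.
#' @param priors optional list overriding elements of the default priors
#'   (`mean_sc_intercept`, `mean_a_intercept`, `sd_intercept`, `sd_effect`,
#'   `cauchy_scale`).
#' @return An object of class `cs_posterior`: draws array
#'   `(iterations x chains x parameters)`, parameter names, split-chain
#'   Rhat per parameter, and the model frame metadata.
#' @export
fit_critical_scale <- function(trials, link, chains = 4, iter = 20000,
                               warmup = 10000, seed = 1, priors = NULL) {
  stopifnot(inherits(link, "link_params"))
  tr <- as.data.frame(trials)
  req <- c("participant", "image", "image_type", "comparison", "model",
           "scale", "n_trials", "n_correct")
  miss <- setdiff(req, names(tr))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tr$model != "FS")) {
    message(sum(tr$model != "FS"),
            " non-FS rows dropped from critical-scale fit")
    tr <- tr[tr$model == "FS", ]
  }
  if (nrow(tr) == 0) stop("no FS trials to fit", call. = FALSE)
  stopifnot(all(tr$scale > 0), all(tr$n_correct >= 0),
            all(tr$n_correct <= tr$n_trials))
  tr$image_type <- factor(tr$image_type, levels = c("scene", "texture"))
  tr$comparison <- factor(tr$comparison,
                          levels = c("orig_vs_synth", "synth_vs_synth"))
  if (anyNA(tr$image_type) || anyNA(tr$comparison))
    stop("unknown image_type or comparison level", call. = FALSE)
  cells <- table(tr$image_type, droplevels(tr$comparison))
  if (any(cells == 0))
    stop("empty condition cell: every image_type x comparison ",
         "combination present in the data must contain trials",
         call. = FALSE)
  # with one comparison level the interaction columns drop out on their own
  form <- if (nlevels(droplevels(tr$comparison)) > 1)
    ~ image_type * comparison else ~ image_type
  X <- stats::model.matrix(form, tr)
  P <- ncol(X)

  pgrp <- interaction(tr$participant, tr$image_type, tr$comparison,
                      drop = TRUE, lex.order = TRUE)
  igrp <- interaction(tr$image, tr$comparison, drop = TRUE,
                      lex.order = TRUE)

  pr <- list(mean_sc_intercept = -0.69, mean_a_intercept = 1,
             sd_intercept = 1, sd_effect = 0.5, cauchy_scale = 0.1)
  pr[names(priors)] <- priors
  pm_sc <- c(pr$mean_sc_intercept, rep(0, P - 1))
  pm_a <- c(pr$mean_a_intercept, rep(0, P - 1))
  psd <- c(pr$sd_intercept, rep(pr$sd_effect, P - 1))

  # each random-effect group sits in exactly one fixed-effect design cell;
  # its design row powers the sampler's likelihood-invariant swap moves
  Gp <- X[match(levels(pgrp), as.character(pgrp)), , drop = FALSE]
  Gi <- X[match(levels(igrp), as.character(igrp)), , drop = FALSE]

  set.seed(seed)
  raw <- run_cs_sampler(
    as.numeric(tr$scale), as.integer(tr$n_trials),
    as.integer(tr$n_correct), X, as.integer(pgrp) - 1L,
    as.integer(igrp) - 1L, nlevels(pgrp), nlevels(igrp), link$lam,
    link$k, 1 / link$m, pm_sc, psd, pm_a, psd, pr$cauchy_scale,
    as.integer(chains), as.integer(iter), as.integer(warmup), Gp, Gi)

  pnames <- c(paste0("b_sc.", colnames(X)), paste0("b_alpha.", colnames(X)),
              paste0("z_p_sc.", levels(pgrp)),
              paste0("z_p_alpha.", levels(pgrp)),
              paste0("z_i_sc.", levels(igrp)),
              paste0("z_i_alpha.", levels(igrp)),
              "log_sd_p_sc", "log_sd_p_alpha", "log_sd_i_sc",
              "log_sd_i_alpha")
  nd <- iter - warmup
  draws <- array(NA_real_, c(nd, chains, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  for (ch in seq_len(chains)) draws[, ch, ] <- raw[[ch]]

  rhat <- apply(draws, 3, split_rhat)
  if (any(rhat > 1.01, na.rm = TRUE))
    warning(sum(rhat > 1.01, na.rm = TRUE),
            " parameters with split-chain Rhat > 1.01; ",
            "inspect convergence (max Rhat = ",
            sprintf("%.3f", max(rhat, na.rm = TRUE)), ")", call. = FALSE)

  structure(list(
    draws = draws, parameters = pnames, rhat = rhat, X_names = colnames(X),
    participant_levels = levels(pgrp), image_levels = levels(igrp),
    image_map = unique(tr[, c("image", "image_type", "comparison")]),
    link = link, formula = form,
    mcmc = list(chains = chains, iter = iter, warmup = warmup,
                seed = seed), priors = pr),
    class = "cs_posterior")
}

#' @export
print.cs_posterior <- function(x, ...) {
  cat(sprintf(
    "<cs_posterior> %d draws x %d chains x %d parameters (max Rhat %.3f)\n",
    dim(x$draws)[1], dim(x$draws)[2], dim(x$draws)[3],
    max(x$rhat, na.rm = TRUE)))
  fx <- grep("^b_", x$parameters, value = TRUE)
  for (p in fx) {
    sm <- summarize_posterior(x, stats::setNames(1, p))
    cat(sprintf("  %-38s %7.3f [%7.3f, %7.3f]\n", p, sm$mean, sm$lower,
                sm$upper))
  }
  invisible(x)
}

# split-chain potential scale reduction (Gelman-Rubin, split halves)
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# draws of a linear combination of parameters, pooled over chains
combo_draws <- function(post, contrast) {
  idx <- match(names(contrast), post$parameters)
  if (anyNA(idx))
    stop("unknown parameter(s): ",
         paste(names(contrast)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  d <- post$draws[, , idx, drop = FALSE]
  m <- matrix(d, ncol = length(idx))
  as.vector(m %*% contrast)
}

#' Summarize a posterior contrast
#'
#' Posterior mean, central 95% credible interval and the posterior
#' probability of being negative (empirical CDF at zero) for a linear
#' combination of model parameters.
#'
#' @param post a `cs_posterior`.
#' @param contrast named numeric vector of coefficients over parameter
#'   names (see `post$parameters`).
#' @param prob credible-interval mass (default 0.95).
#' @return list with `mean`, `lower`, `upper`, `p_negative`.
#' @export
summarize_posterior <- function(post, contrast, prob = 0.95) {
  v <- combo_draws(post, contrast)
  qs <- stats::quantile(v, c((1 - prob) / 2, 1 - (1 - prob) / 2),
                        names = FALSE)
  list(mean = mean(v), lower = qs[1], upper = qs[2],
       p_negative = mean(v < 0))
}

# fixed-effect design row for a condition cell, as a contrast over b_ names
cell_contrast <- function(post, image_type, comparison, param = "sc") {
  nm <- post$X_names
  v <- stats::setNames(numeric(length(nm)), paste0("b_", param, ".", nm))
  v[1] <- 1
  it <- paste0("image_type", image_type)
  cmp <- paste0("comparison", comparison)
  v[paste0("b_", param, ".", nm)[nm %in% c(it, cmp, paste0(it, ":", cmp))]] <- 1
  v
}

#' Population critical scale per condition
#'
#' Posterior summary of `exp(log s_c)` at the population level (zero
#' random-effect offsets) for one condition cell.
#'
#' @param post a `cs_posterior`.
#' @param image_type `"scene"` or `"texture"`.
#' @param comparison `"orig_vs_synth"` or `"synth_vs_synth"`.
#' @param param `"sc"` (critical scale) or `"alpha"` (gain).
#' @return list with `mean`, `lower`, `upper` on the natural scale.
#' @export
population_scale <- function(post, image_type, comparison, param = "sc") {
  v <- exp(combo_draws(post, cell_contrast(post, image_type, comparison,
                                           param)))
  qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
  list(mean = mean(v), lower = qs[1], upper = qs[2])
}

#' Scene-vs-texture critical-scale difference
#'
#' Per-draw difference `s_c(texture) - s_c(scene)` on the natural scale
#' within one comparison condition, summarized as mean, 95% CI and
#' `p(difference < 0)`.
#'
#' @param post a `cs_posterior`.
#' @param comparison condition to contrast within.
#' @return list with `mean`, `lower`, `upper`, `p_negative`.
#' @export
critical_scale_difference <- function(post,
                                      comparison = "orig_vs_synth") {
  vt <- exp(combo_draws(post, cell_contrast(post, "texture", comparison)))
  vs <- exp(combo_draws(post, cell_contrast(post, "scene", comparison)))
  dif <- vt - vs
  qs <- stats::quantile(dif, c(0.025, 0.975), names = FALSE)
  list(mean = mean(dif), lower = qs[1], upper = qs[2],
       p_negative = mean(dif < 0))
}

#' Image-level critical scales and the system critical scale
#'
#' For every image x comparison cell, the posterior mean of
#' `exp(population + condition effects + image offset)` — the
#' image-specific critical scale `s_crit(I)` — and, per condition, the
#' minimum over images (`s_system`), the binding constraint for an
#' image-independent pooling theory.
#'
#' @param post a `cs_posterior`.
#' @return list with `per_image` (data.frame: image, image_type,
#'   comparison, s_crit) and `s_system` (data.frame: comparison,
#'   image_type, s_system, image attaining it).
#' @export
image_critical_scales <- function(post) {
  map <- post$image_map
  sd_i <- exp(as.vector(post$draws[, , "log_sd_i_sc"]))
  out <- map
  out$s_crit <- NA_real_
  for (r in seq_len(nrow(map))) {
    lev <- paste(map$image[r], map$comparison[r], sep = ".")
    zc <- paste0("z_i_sc.", lev)
    base <- combo_draws(post, cell_contrast(post, map$image_type[r],
                                            map$comparison[r]))
    z <- as.vector(post$draws[, , zc])
    out$s_crit[r] <- mean(exp(base + sd_i * z))
  }
  agg <- do.call(rbind, lapply(
    split(out, list(out$comparison, out$image_type), drop = TRUE),
    function(d) data.frame(comparison = d$comparison[1],
                           image_type = d$image_type[1],
                           s_system = min(d$s_crit),
                           image = d$image[which.min(d$s_crit)])))
  rownames(agg) <- NULL
  list(per_image = out, s_system = agg)
}
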