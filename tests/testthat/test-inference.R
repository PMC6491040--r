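# quick-fit settings for module-level tests; the acceptance suite runs the
# criterion-level 4 x 2000 regime
quick_fit <- function(tab, lk, seed = 3, chains = 2, iter = 1200,
                      warmup = 600)
  suppressWarnings(fit_critical_scale(tab, lk, chains = chains,
                                      iter = iter, warmup = warmup,
                                      seed = seed))

small_gp <- function(...) generating_params(
  n_participants = 4, n_images_per_type = 4,
  scales = c(0.25, 0.46, 0.86, 1.45), trials_per_cell = 8,
  comparisons = "orig_vs_synth", ...)

test_that("summarize_posterior computes mean, CI and p(beta<0)", {
  fake <- structure(list(
    draws = array(c(-1, 1, 3), c(3, 1, 1),
                  dimnames = list(NULL, NULL, "b")),
    parameters = "b"), class = "cs_posterior")
  sm <- summarize_posterior(fake, c(b = 1))
  expect_equal(sm$mean, 1)
  expect_equal(sm$p_negative, 1 / 3)

  sym <- structure(list(
    draws = array(c(-2, -1, 1, 2), c(4, 1, 1),
                  dimnames = list(NULL, NULL, "b")),
    parameters = "b"), class = "cs_posterior")
  expect_equal(summarize_posterior(sym, c(b = 1))$p_negative, 0.5)

  pos <- structure(list(
    draws = array(1:5, c(5, 1, 1), dimnames = list(NULL, NULL, "b")),
    parameters = "b"), class = "cs_posterior")
  expect_equal(summarize_posterior(pos, c(b = 1))$p_negative, 0)
  expect_error(summarize_posterior(pos, c(nope = 1)), "unknown")
})

test_that("prior center corresponds to a critical scale of about 0.5", {
  expect_equal(exp(-0.69), 0.5, tolerance = 0.01)
})

test_that("the model recovers generating parameters on a small design", {
  lk <- cached_link()
  # truths inside the tested scale range, so the small design is
  # informative about both parameters (truths at or below the smallest
  # tested scale are only bounded from above, not located)
  gp <- small_gp(seed = 31,
                 s_c = c(orig_vs_synth.scene = 0.4,
                         orig_vs_synth.texture = 0.6),
                 alpha = c(orig_vs_synth.scene = 2.7,
                           orig_vs_synth.texture = 2.7))
  tab <- gen_trials(gp, lk)
  post <- quick_fit(tab, lk)
  for (ty in c("scene", "texture")) {
    ps <- population_scale(post, ty, "orig_vs_synth")
    tru <- gp$s_c[paste0("orig_vs_synth.", ty)]
    expect_lt(abs(ps$mean - tru) / tru, 0.30)   # loose: tiny design
    expect_true(ps$lower <= tru && tru <= ps$upper)
  }
  # gain recovered in order of magnitude
  pa <- population_scale(post, "scene", "orig_vs_synth", param = "alpha")
  expect_gt(pa$mean, 1); expect_lt(pa$mean, 6)
  # rhat reported for every parameter
  expect_equal(length(post$rhat), dim(post$draws)[3])
  expect_true(all(is.finite(post$rhat) | is.na(post$rhat)))
})

test_that("chance-level data push the critical scale out of the tested range", {
  lk <- cached_link()
  set.seed(5)
  tab <- expand.grid(participant = sprintf("p%d", 1:4),
                     image = sprintf("i%d", 1:4),
                     comparison = "orig_vs_synth",
                     scale = c(0.25, 0.46, 0.86, 1.45),
                     stringsAsFactors = FALSE)
  tab$image_type <- ifelse(tab$image %in% c("i1", "i2"), "scene",
                           "texture")
  tab$model <- "FS"
  tab$n_trials <- 20L
  tab$n_correct <- rbinom(nrow(tab), 20L, 1 / 3)
  post <- quick_fit(tab, lk, iter = 1500, warmup = 750)
  sc <- exp(as.vector(post$draws[, , "b_sc.(Intercept)"]))
  # essentially no mass below the smallest tested scale ...
  expect_lt(mean(sc < 0.25), 0.05)
  # ... and mass above the largest tested scale well beyond its prior
  # share (prior: log s_c ~ N(-0.69, 1) puts ~0.14 above 1.45)
  expect_gt(mean(sc > 1.45), 0.25)
  expect_gt(median(sc), 2 * exp(-0.69))
})

test_that("fit is stable under row order and label permutation", {
  lk <- cached_link()
  gp <- small_gp(seed = 32)
  tab <- gen_trials(gp, lk)
  p1 <- quick_fit(tab, lk, seed = 6)
  set.seed(1)
  shuf <- tab[sample(nrow(tab)), ]
  relab <- shuf
  relab$participant <- paste0("Q", relab$participant)
  relab$image <- paste0("Z", relab$image)
  p2 <- quick_fit(relab, lk, seed = 6)
  for (ty in c("scene", "texture")) {
    a <- population_scale(p1, ty, "orig_vs_synth")$mean
    b <- population_scale(p2, ty, "orig_vs_synth")$mean
    expect_lt(abs(a - b) / a, 0.08)   # identical model, MC error only
  }
})

test_that("group sds shrink under zero heterogeneity and CIs tighten with data", {
  lk <- cached_link()
  gp0 <- generating_params(participant_sd = 0, image_sd = 0,
                           n_participants = 6, n_images_per_type = 6,
                           trials_per_cell = 8,
                           comparisons = "orig_vs_synth", seed = 2)
  tab <- gen_trials(gp0, lk)
  p1 <- quick_fit(tab, lk, seed = 4, chains = 4, iter = 2000,
                  warmup = 1000)
  expect_lt(mean(exp(as.vector(p1$draws[, , "log_sd_p_sc"]))), 0.1)
  expect_lt(mean(exp(as.vector(p1$draws[, , "log_sd_i_sc"]))), 0.1)

  tab2 <- tab
  tab2$n_trials <- tab$n_trials * 2L
  tab2$n_correct <- tab$n_correct * 2L
  p2 <- quick_fit(tab2, lk, seed = 4, chains = 4, iter = 2000,
                  warmup = 1000)
  s1 <- sd(as.vector(p1$draws[, , "b_sc.(Intercept)"]))
  s2 <- sd(as.vector(p2$draws[, , "b_sc.(Intercept)"]))
  expect_lt(s2, s1)
})

test_that("image-level critical scales track their offsets", {
  lk <- cached_link()
  gp <- small_gp(seed = 33, image_sd = 0.3)
  tab <- gen_trials(gp, lk)
  post <- quick_fit(tab, lk)
  ics <- image_critical_scales(post)
  expect_equal(nrow(ics$per_image), 8)   # 8 images x 1 comparison
  expect_true(all(ics$per_image$s_crit > 0))
  # s_system is the minimum over images within its condition
  for (r in seq_len(nrow(ics$s_system))) {
    sel <- ics$per_image$image_type == ics$s_system$image_type[r]
    expect_equal(ics$s_system$s_system[r],
                 min(ics$per_image$s_crit[sel]))
  }
})

test_that("malformed trial tables are rejected", {
  lk <- cached_link()
  expect_error(fit_critical_scale(data.frame(a = 1), lk), "lacks columns")
  gp <- small_gp(seed = 34)
  tab <- gen_trials(gp, lk)
  bad <- tab
  bad$image_type <- "landscape"
  expect_error(fit_critical_scale(bad, lk), "unknown image_type")
  onecell <- tab[tab$image_type == "scene", ]
  expect_error(fit_critical_scale(onecell, lk), "empty condition cell")
  cnn <- tab
  cnn$model[1:10] <- "CNN32"
  expect_message(quick_fit(cnn, lk), "non-FS rows dropped")
})
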