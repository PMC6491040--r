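test_that("gen_trials is deterministic and respects the plateau", {
  lk <- cached_link()
  gp <- generating_params(seed = 7)
  t1 <- gen_trials(gp, lk)
  t2 <- gen_trials(gp, lk)
  expect_identical(t1, t2)
  t3 <- gen_trials(generating_params(seed = 8), lk)
  expect_false(identical(t1$n_correct, t3$n_correct))
  expect_equal(nrow(t1), 8 * 20 * 2 * 8)
  expect_true(all(t1$n_correct >= 0 & t1$n_correct <= t1$n_trials))

  # all scales at or below the critical scale: every cell binomial(1/3)
  gp0 <- generating_params(
    s_c = c(orig_vs_synth.scene = 2, orig_vs_synth.texture = 2),
    alpha = c(orig_vs_synth.scene = 2.7, orig_vs_synth.texture = 2.7),
    participant_sd = 0, image_sd = 0, comparisons = "orig_vs_synth",
    scales = c(0.25, 0.86, 1.45), seed = 9)
  tp <- gen_trials(gp0, lk)
  expect_equal(unique(unname(attr(tp, "truth")$p)), 1 / 3)
})

test_that("empirical proportions converge to the link predictions", {
  lk <- cached_link()
  gp <- generating_params(participant_sd = 0, image_sd = 0,
                          n_participants = 1, n_images_per_type = 1,
                          scales = c(0.3, 0.5, 0.9, 1.45),
                          trials_per_cell = 1e5,
                          comparisons = "orig_vs_synth", seed = 10)
  tab <- gen_trials(gp, lk)
  key <- paste(tab$comparison, tab$image_type, sep = ".")
  pred <- weibull_pc(dprime_of_scale(tab$scale, gp$s_c[key],
                                     gp$alpha[key]), lk)
  expect_lt(max(abs(tab$n_correct / tab$n_trials - pred)), 0.01)
})

test_that("texture-like images are stationary, scene-like are not", {
  img <- gen_image(128, "texture_like", 5)
  expect_identical(img$pixels, gen_image(128, "texture_like", 5)$pixels)
  expect_lt(abs(mean(img$pixels) - 0.5), 1e-9)
  sdev <- sqrt(mean((img$pixels - 0.5)^2))
  expect_lt(abs(sdev / 0.5 - 0.3), 1e-9)

  tile_stat <- function(x, f) {
    n <- nrow(x) / 4
    vapply(0:15, function(i) {
      r <- (i %% 4) * n; c <- (i %/% 4) * n
      f(x[(r + 1):(r + n), (c + 1):(c + n)])
    }, numeric(1))
  }
  # patchwise contrast: coefficient of variation below 0.3
  contr <- tile_stat(img$pixels, sd)
  expect_lt(sd(contr) / mean(contr), 0.3)

  # scene-like: edge density significantly non-uniform over tiles
  scn <- gen_image(128, "scene_like", 5)
  edge_count <- function(x) {
    gx <- abs(x[, -1] - x[, -ncol(x)])
    sum(gx > quantile(gx, 0.95))
  }
  counts <- tile_stat(scn$pixels, edge_count)
  expect_lt(chisq.test(counts)$p.value, 0.01)
  # and its patchwise contrast is more variable than the texture's
  contr_s <- tile_stat(scn$pixels, sd)
  expect_gt(sd(contr_s) / mean(contr_s), sd(contr) / mean(contr))
})
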