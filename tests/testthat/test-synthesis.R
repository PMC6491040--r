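test_that("pool_statistics obeys degenerate and locality contracts", {
  g <- build_polar_grid(64, 4, 3, 8)
  bk <- filterbank_backend(input_sizes = 64, n_scales = 2)
  # constant image: every region mean equal within each channel
  st <- pool_statistics(gray_image(matrix(0.4, 64, 64)), g, bk)
  by_ch <- split(st$values, st$index$channel)
  for (v in by_ch) expect_lt(diff(range(v)), 1e-12)

  # single-region grid: pooled value equals the feature mean over the mask
  set.seed(6)
  x <- matrix(runif(64^2), 64, 64)
  g1 <- build_polar_grid(64, 1, 1, 8)
  idb <- identity_backend()
  st1 <- pool_statistics(gray_image(x), g1, idb)
  expect_equal(st1$values, mean(x[g1$labels == 1L]))

  # locality: images identical inside a region give identical stats there
  y <- x
  outside <- g$labels == n_regions(g)   # corrupt one far region only
  y[outside] <- runif(sum(outside))
  sa <- pool_statistics(gray_image(x), g, idb)
  sb <- pool_statistics(gray_image(y), g, idb)
  same <- sa$index$region != n_regions(g)
  expect_equal(sa$values[same], sb$values[same])
  expect_false(isTRUE(all.equal(sa$values[!same], sb$values[!same])))
})

test_that("rotation permutes pooled stats with an equivariant backend", {
  set.seed(7)
  g <- build_polar_grid(64, 4, 3, 8)
  idb <- identity_backend()
  x <- matrix(runif(64^2), 64, 64)
  sa <- matrix(pool_statistics(gray_image(x), g, idb)$values, nrow = 12)
  sb <- matrix(pool_statistics(gray_image(rot90_raster(x)), g,
                               idb)$values, nrow = 12)
  perm <- function(v, k) {  # shift angular index within each ring
    idx <- (seq_len(12) - 1)
    r <- idx %/% 4; a <- idx %% 4
    v[r * 4 + ((a + k) %% 4) + 1]
  }
  hit <- vapply(0:3, function(k) isTRUE(all.equal(as.vector(sb),
                                                  perm(as.vector(sa), k))),
                logical(1))
  expect_true(any(hit[-1]) || isTRUE(all.equal(as.vector(sb),
                                               as.vector(sa))))
})

test_that("normalized_mse matches its closed forms and a brute oracle", {
  set.seed(8)
  a <- matrix(rnorm(100), 10, 10)
  expect_equal(normalized_mse(a, a), 0)
  expect_equal(normalized_mse(a, a + 0.3),
               0.3^2 / mean((a - mean(a))^2), tolerance = 1e-12)
  b <- matrix(rnorm(100), 10, 10)
  # independent two-line oracle
  oracle <- sum((a - b)^2) / length(a) / (sum((a - mean(a))^2) / length(a))
  expect_lt(abs(normalized_mse(a, b) - oracle), 1e-12)
  expect_error(normalized_mse(matrix(1, 3, 3), matrix(0, 3, 3)),
               "zero-variance")
  expect_error(normalized_mse(1:4, 1:5), "shape")
})

test_that("synthesize_pooled holds its fixed point and pinned disk", {
  set.seed(9)
  img <- gen_image(64, "texture_like", 2)
  g <- build_polar_grid(64, 4, 3, 8)
  bk <- filterbank_backend(input_sizes = 64, n_scales = 2)
  target <- pool_statistics(img, g, bk)
  # init at the original: loss 0 at step 0, output identical
  fp <- synthesize_pooled(target, img, g, bk, n_steps = 5,
                          pinned_radius = 8, init = img)
  expect_equal(attr(fp, "loss")[1], 0)
  expect_equal(fp$pixels, img$pixels)

  out <- synthesize_pooled(target, img, g, bk, n_steps = 40,
                           pinned_radius = 8, seed = 3)
  l <- attr(out, "loss")
  expect_true(all(diff(l) <= 0))          # monotone accepted steps
  expect_lt(l[length(l)], 0.5 * l[1])
  pin <- ecc_map(64) <= 8
  expect_identical(out$pixels[pin], img$pixels[pin])
  # non-differentiable backend refused
  ndb <- identity_backend(); ndb$differentiable <- FALSE
  expect_error(synthesize_pooled(target, img, g, ndb, 5), "gradient")
})

test_that("gram matrices are PSD and local distortion is local", {
  set.seed(10)
  img <- gen_image(128, "scene_like", 4)
  bk <- filterbank_backend(input_sizes = 128, n_scales = 2)
  gs <- gram_stats(img, bk)
  for (G in gs) {
    expect_equal(G, t(G))
    expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }

  ctr <- c(64, 64); radius <- 24
  out <- make_local_distortion(img, ctr, radius, bk, n_steps = 30,
                               seed = 5)
  xs <- seq_len(128) - 1
  dist <- sqrt(outer((xs - ctr[2])^2, (xs - ctr[1])^2, "+"))
  expect_identical(out$pixels[dist >= radius], img$pixels[dist >= radius])
  expect_false(isTRUE(all.equal(out$pixels[dist < radius - 12],
                                img$pixels[dist < radius - 12])))
  expect_true(all(diff(attr(out, "loss")) <= 0))
  # statistics window side length: 2 * (radius + margin)
  expect_error(make_local_distortion(img, c(5, 5), 40, bk, n_steps = 1),
               "bounds")
})
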