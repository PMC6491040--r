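test_that("filter_trials drops and attributes by rule, conserving rows", {
  raw <- make_raw(10, no_resp = 2, fix_break = 1)
  res <- filter_trials(raw)
  expect_equal(res$report$n_input, 10)
  expect_equal(res$report$dropped$no_response, 2)
  expect_equal(res$report$dropped$fixation_break, 1)
  expect_equal(res$report$n_retained, 7)
  expect_equal(res$report$n_retained + res$report$dropped$no_response +
                 res$report$dropped$fixation_break, res$report$n_input)
  # aggregation conserves trials
  expect_equal(sum(res$table$n_trials), res$report$n_retained)

  # a row with both flags is attributed to no-response; retained set is
  # unaffected by attribution order
  both <- make_raw(6, no_resp = 1)
  both$fixation_break[1] <- TRUE
  r2 <- filter_trials(both)
  expect_equal(r2$report$dropped$no_response, 1)
  expect_equal(r2$report$dropped$fixation_break, 0)
  expect_equal(r2$report$n_retained, 5)

  empty <- filter_trials(make_raw(0))
  expect_equal(empty$report$n_retained, 0)
  expect_equal(nrow(empty$table), 0)

  expect_error(filter_trials(data.frame(a = 1)), "lacks columns")
})

test_that("experiment-2 style tables aggregate on radius", {
  raw <- make_raw(8)
  raw$scale <- NULL
  raw$radius <- rep(c(40, 100), each = 4)
  keys <- c("participant", "image", "image_type", "comparison", "model",
            "radius")
  res <- filter_trials(raw, cell_keys = keys)
  expect_setequal(res$table$radius, c(40, 100))
  expect_equal(sum(res$table$n_trials), 8)
})

test_that("pc_by_condition averages observer means with SEM", {
  tab <- data.frame(
    participant = c("a", "a", "b"), image = "i1", image_type = "scene",
    comparison = "orig_vs_synth", model = "FS", scale = 0.5,
    n_trials = c(10, 10, 10), n_correct = c(3, 5, 6))
  out <- pc_by_condition(tab, "scale")
  expect_equal(out$pc, mean(c(8 / 20, 6 / 10)))   # 0.4 and 0.6 -> 0.5
  expect_equal(out$sem, sd(c(0.4, 0.6)) / sqrt(2))  # 0.1
  expect_equal(out$n_observers, 2)
  # single observer: SEM undefined
  one <- pc_by_condition(tab[3, ], "scale")
  expect_true(is.na(one$sem))
  expect_equal(one$pc, 0.6)
  # row-order invariance
  out2 <- pc_by_condition(tab[c(3, 1, 2), ], "scale")
  expect_equal(out2, out)
})

test_that("trial tables and schema adapter roundtrip through CSV", {
  lk <- cached_link()
  gp <- generating_params(n_participants = 2, n_images_per_type = 2,
                          scales = c(0.3, 0.8), seed = 4)
  tab <- gen_trials(gp, lk)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(tab, path)
  back <- read_trials_csv(path)
  expect_equal(back$n_correct, tab$n_correct)

  # dialect mapping: canonical <- file column; extras pass through
  alien <- tab
  names(alien)[names(alien) == "participant"] <- "subj"
  alien$extra <- 1
  write_trials_csv(alien, path)
  mapped <- read_trials_csv(path, schema = c(participant = "subj"))
  expect_true("participant" %in% names(mapped))
  expect_true("extra" %in% names(mapped))
  expect_equal(mapped$participant, tab$participant)
})
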