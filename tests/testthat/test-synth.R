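test_that("generated dataset has the configured shape, labels and onset", {
  cfg <- synth_config(n_subjects = 2, trials_per_condition = 3,
                      n_channels = 4, sample_rate = 1000,
                      epoch_span = c(-200, 800),
                      band_plan = test_band_plan(), seed = 5)
  ep <- generate_dataset(cfg)
  expect_s3_class(ep, "epoch_set")
  expect_equal(dim(ep$data), c(2 * 3 * 3, 4, 1000))
  expect_equal(unname(table(ep$condition)), rep(6L, 3),
               ignore_attr = TRUE)
  expect_equal(ep$time_zero_index, 201L)
  expect_true(all(is.finite(ep$data)))
  expect_length(ep$channel_labels, 4)
})

test_that("regeneration with the same seed is bit-identical", {
  cfg <- synth_config(trials_per_condition = 2, n_channels = 3,
                      band_plan = test_band_plan(), seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$data, b$data)
  cfg2 <- synth_config(trials_per_condition = 2, n_channels = 3,
                       band_plan = test_band_plan(), seed = 10)
  expect_false(identical(generate_dataset(cfg2)$data, a$data))
})

test_that("experiment arithmetic reproduces the design counts", {
  expect_equal(experiment_counts(28, 48, 6), 8064)
  expect_equal(experiment_counts(1, 1, 1), 1)
  expect_equal(experiment_counts(1, 16, 18), 288)
  expect_error(experiment_counts(0, 1, 1), "positive")
})

test_that("stratified split reproduces the 70/30 per-category counts", {
  n_per <- 7665
  dat <- array(rnorm(2 * n_per * 1 * 2), c(2 * n_per, 1, 2))
  ep <- epoch_set(dat, 1000, 1, "Ch01",
                  condition = rep(c("face", "ketch"), each = n_per),
                  subject = rep("s01", 2 * n_per))
  sp <- split_dataset(ep, 0.7, seed = 4)
  expect_equal(unname(table(sp$analysis$condition)), c(5366L, 5366L),
               ignore_attr = TRUE)
  expect_equal(unname(table(sp$holdout$condition)), c(2299L, 2299L),
               ignore_attr = TRUE)
  # disjoint and exhaustive
  expect_equal(n_trials(sp$analysis) + n_trials(sp$holdout), 2 * n_per)
  sp2 <- split_dataset(ep, 0.7, seed = 4)
  expect_identical(sp$analysis$data, sp2$analysis$data)
})

test_that("a balanced half split is disjoint and exhaustive", {
  dat <- array(seq_len(10 * 1 * 4), c(10, 1, 4))
  ep <- epoch_set(dat, 1000, 1, "Ch01",
                  condition = rep("all", 10))
  sp <- split_dataset(ep, 0.5, seed = 1)
  expect_equal(n_trials(sp$analysis), 5)
  expect_equal(n_trials(sp$holdout), 5)
  first <- sp$analysis$data[, 1, 1]
  second <- sp$holdout$data[, 1, 1]
  expect_length(intersect(first, second), 0)
  expect_setequal(c(first, second), dat[, 1, 1])
  tiny <- epoch_set(array(rnorm(4), c(1, 1, 4)), 1000, 1, "Ch01")
  expect_error(split_dataset(tiny, 0.5), "fewer than 2")
})

test_that("zero coupling strength leaves channel phases unsynchronized", {
  # noise-dominated signals: instantaneous phase decorrelates within a
  # few samples, so the 100-sample null PLI sits near sqrt(2/(pi N))
  cfg <- synth_config(n_subjects = 1, trials_per_condition = 30,
                      n_channels = 4, band_plan = test_band_plan(),
                      coupling_strength = 0, noise_sd = 30, seed = 2)
  ep <- generate_dataset(cfg)
  vals <- c()
  for (i in seq_len(n_trials(ep))) {
    ph <- t(apply(ep$data[i, , ], 1,
                  function(ch) analytic_phase(ch)$phase))
    idx <- 201:300
    m <- pli_matrix(ph[, idx])
    vals <- c(vals, m[upper.tri(m)])
  }
  expect_lte(mean(vals), 0.1)
})

test_that("coupling graphs and plans are validated", {
  expect_error(coupling_graph(4, data.frame(i = 1, j = 1, lag = 1,
                                            weight = 1)), "self-edge")
  expect_error(coupling_graph(4, data.frame(i = c(1, 2), j = c(2, 1),
                                            lag = 1, weight = 1)),
               "duplicate")
  expect_error(coupling_graph(4, data.frame(i = 1, j = 2, lag = 4,
                                            weight = 1)), "lag")
  expect_error(coupling_graph(4, data.frame(i = 1, j = 2, lag = 1,
                                            weight = 2)), "weight")
  g <- star_coupling(4)
  expect_error(synth_config(n_channels = 4,
                            band_plan = test_band_plan(),
                            coupling_plan = list(
                              face = list(gamma = list("9" = g)))),
               "outside")
  expect_error(synth_config(n_channels = 6,
                            band_plan = test_band_plan(),
                            coupling_plan = list(
                              face = list(gamma = list("2" = g)))),
               "n_channels")
  expect_error(synth_config(epoch_span = c(100, 800)), "start < 0")
})

test_that("epoch archive round-trips through disk", {
  cfg <- synth_config(trials_per_condition = 2, n_channels = 3,
                      epoch_span = c(-50, 150), n_windows = 1,
                      band_plan = list(gamma = c(31, 46)), seed = 3)
  ep <- generate_dataset(cfg)
  dir <- tempfile("archive")
  write_epoch_archive(ep, dir)
  back <- read_epoch_archive(dir)
  expect_equal(back$data, ep$data, tolerance = 1e-12)
  expect_identical(back$condition, ep$condition)
  expect_identical(back$channel_labels, ep$channel_labels)
  expect_equal(back$time_zero_index, ep$time_zero_index)
  unlink(dir, recursive = TRUE)
})
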