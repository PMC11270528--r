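make_pair <- function(seed = 1) {
  lib <- default_metabolite_library()
  hr <- local({ set.seed(seed); simulate_mixture(lib, 6, demo_grid()) })
  list(hr = hr, lr = degrade(hr))
}

test_that("patch selection keeps only peak-containing, aligned crops", {
  pr <- make_pair()
  # all-zero spectrum: nothing to train on
  z <- jres_spectrum(matrix(0, 64, 1024), demo_grid()$f1, demo_grid()$f2)
  expect_length(select_training_patches(z, degrade(z), 64, n = 10, seed = 1),
                0)
  ps <- select_training_patches(pr$hr, pr$lr, 64, n = 20, seed = 2)
  expect_gt(length(ps), 0)
  for (p in ps) {
    expect_identical(dim(p$hr), c(64L, 64L))
    expect_identical(dim(p$lr), c(32L, 32L))
    expect_true(all(p$origin %% 2 == 0))
    expect_gt(max(p$hr), 0.05 * max(pr$hr$grid))
    # LR patch is the co-located half-size crop
    expect_identical(p$lr,
                     pr$lr$grid[p$origin[1] / 2 + 1:32,
                                p$origin[2] / 2 + 1:32, drop = FALSE])
  }
  # a single dominant peak: kept patches contain its pixel
  g <- matrix(0, 64, 1024); g[32, 500] <- 1
  sp <- jres_spectrum(g, demo_grid()$f1, demo_grid()$f2)
  kept <- select_training_patches(sp, degrade(sp), 64, n = 200, seed = 3)
  expect_gt(length(kept), 0)
  for (p in kept) {
    expect_true(p$origin[2] <= 499 && 499 < p$origin[2] + 64)
  }
  expect_error(select_training_patches(pr$hr, pr$lr, 2048), "larger")
})

test_that("training rejects bad inputs and reduces the supervised loss", {
  pr <- make_pair()
  expect_error(train(list(pr), 0), "iterations")
  expect_error(train(list(), 5), "empty")
  # supervised regression (no GAN): smoothed loss decreases over the run
  fx <- demo_fixture(seed = 1)
  st <- train(fx$pairs, iterations = 200,
              weights = loss_weights(w_gan = 0), lr = 2e-3, seed = 1)
  h <- st$history$total
  expect_lt(mean(tail(h, 50)), mean(head(h, 50)))
  expect_equal(nrow(st$history), 200)
  # training is deterministic for a fixed seed
  sa <- train(fx$pairs[1:4], iterations = 5, lr = 2e-3, seed = 3)
  sb <- train(fx$pairs[1:4], iterations = 5, lr = 2e-3, seed = 3)
  expect_identical(sa$history, sb$history)
  expect_identical(sa$gen, sb$gen)
})

test_that("training with the GAN branch records both adversarial terms", {
  pr <- make_pair()
  st <- train(list(pr), iterations = 8, lr = 1e-3, seed = 8)
  expect_true(all(is.finite(st$history$gan_g)))
  expect_true(all(is.finite(st$history$gan_d)))
  expect_true(all(st$history$gan_d > 0))
})

test_that("enhance doubles dimensions, is deterministic, and handles zeros", {
  pr <- make_pair(2)
  st <- train(list(pr), iterations = 10, weights = loss_weights(w_gan = 0),
              lr = 1e-3, seed = 9)
  sr <- enhance(pr$lr, st)
  expect_identical(dim(sr), c(64L, 1024L))
  expect_equal(sr$f1_axis$start, pr$lr$f1_axis$start)
  expect_equal(sr$f2_axis$end, pr$lr$f2_axis$end)
  expect_equal(sr$f1_axis$n_points, 64L)
  sr2 <- enhance(pr$lr, st)
  expect_identical(sr$grid, sr2$grid)
  z <- jres_spectrum(matrix(0, 32, 512), jres_axis(32, -39, 39, "Hz"),
                     jres_axis(512, -3.56, 13.129, "ppm"))
  expect_true(all(is.finite(enhance(z, st)$grid)))
  expect_error(enhance(pr$lr, list()), "trained")
})

test_that("tiled enhancement matches whole-grid output", {
  pr <- make_pair(3)
  st <- train(list(pr), iterations = 10, weights = loss_weights(w_gan = 0),
              lr = 1e-3, seed = 10)
  full <- enhance(pr$lr, st, tile = ncol(pr$lr$grid))
  tiled <- enhance(pr$lr, st, tile = 128, tile_overlap = 16)
  ref <- max(abs(full$grid))
  expect_lt(max(abs(full$grid - tiled$grid)) / ref, 1e-4)
})

test_that("the symmetric loss term does not worsen SR symmetry", {
  # same seed and data, with and without the symmetry term in the objective
  fx <- demo_fixture(seed = 1)
  st_sym <- train(fx$pairs, iterations = 200, lr = 2e-3, seed = 1)
  st_0 <- train(fx$pairs, iterations = 200, lr = 2e-3, seed = 1,
                weights = loss_weights(w_symmetric = 0))
  tds <- build_dataset(mixture_config(c(1, 3, 6, 9, 12, 15), 1, demo_grid(),
                                      seed = 101),
                       default_metabolite_library())
  sym_of <- function(st) mean(vapply(tds$spectra, function(hr)
    symmetric_loss(enhance(degrade(hr), st)), numeric(1)))
  expect_lte(sym_of(st_sym), sym_of(st_0) + 1e-8)
})
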