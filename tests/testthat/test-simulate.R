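test_that("rendered metabolites are symmetric with the expected integral", {
  grid <- demo_grid()
  m <- jres_metabolite("glc_like",
                       list(jres_multiplet(5.2, 7, proton_weight = 2,
                                           lw_f1 = 2.5, lw_f2 = 0.08)))
  s <- render_metabolite(m, grid)
  # mirror symmetry about J = 0
  expect_lt(max(abs(s$grid - flip_f1(s)$grid)), 1e-6 * max(abs(s$grid)))
  # grid total x pixel area approximates the analytic lineshape integral
  # (= proton weight, each 1D profile having unit integral); linewidths are
  # chosen a few pixels wide so the Riemann sum is accurate
  area <- abs(pixel_width(grid$f1) * pixel_width(grid$f2))
  expect_equal(sum(s$grid) * area, 2, tolerance = 0.01)
})

test_that("a doublet renders as two maxima J/pixel_width rows apart", {
  grid <- demo_grid()
  m <- jres_metabolite("doub", list(jres_multiplet(5, 7, lw_f1 = 1.5,
                                                   lw_f2 = 0.05)))
  s <- render_metabolite(m, grid)
  pk <- pick_peaks(s, 0.1)
  expect_equal(nrow(pk), 2)
  # maxima land on pixel centres, so allow 1 px of discretization
  expect_lte(abs(abs(diff(pk$row)) - 7 / abs(pixel_width(grid$f1))), 1)
  expect_equal(pk$col[1], pk$col[2])
})

test_that("degenerate metabolites render and sample correctly", {
  grid <- demo_grid()
  empty <- jres_metabolite("none", list())
  expect_true(all(render_metabolite(empty, grid)$grid == 0))
  out <- jres_metabolite("out", list(jres_multiplet(20, 7)))
  expect_error(render_metabolite(out, grid), "outside F2")
  # concentration sampling: exact at sd 0, truncated at 0, unbiased
  fixed <- jres_metabolite("f", list(), conc_mean = 2.5, conc_sd = 0)
  expect_identical(sample_concentration(fixed), 2.5)
  set.seed(3)
  lowmean <- jres_metabolite("l", list(), conc_mean = 0.1, conc_sd = 1)
  draws <- replicate(500, sample_concentration(lowmean))
  expect_true(all(draws >= 0))
  normal <- jres_metabolite("n", list(), conc_mean = 1, conc_sd = 0.2)
  draws <- replicate(10000, sample_concentration(normal))
  expect_lt(abs(mean(draws) - 1), 3 * 0.2 / sqrt(10000))
})

test_that("mixtures are linear in concentrations and reproducible", {
  grid <- demo_grid()
  lib <- default_metabolite_library(5)
  r1 <- render_metabolite(lib[[1]], grid)
  # concentration (1, 0): equals the first member's rendered spectrum
  s10 <- simulate_mixture(lib, 2, grid, concentrations = c(1, 0))
  expect_equal(s10$grid, r1$grid, tolerance = 1e-6)
  # homogeneity and additivity
  c1 <- c(1, 0.5, 2); c2 <- c(0.2, 1.4, 0.1)
  sa <- simulate_mixture(lib, 3, grid, concentrations = c1)
  sb <- simulate_mixture(lib, 3, grid, concentrations = c2)
  sab <- simulate_mixture(lib, 3, grid, concentrations = c1 + c2)
  expect_equal(sab$grid, sa$grid + sb$grid, tolerance = 1e-5)
  s2x <- simulate_mixture(lib, 3, grid, concentrations = 2 * c1)
  expect_equal(s2x$grid, 2 * sa$grid, tolerance = 1e-6)
  # fixed seed: identical grids
  g1 <- local({ set.seed(9); simulate_mixture(lib, 3, grid) })
  g2 <- local({ set.seed(9); simulate_mixture(lib, 3, grid) })
  expect_identical(g1$grid, g2$grid)
})

test_that("build_dataset produces counts x reps spectra reproducibly", {
  grid <- jres_grid(16, 128)
  lib <- default_metabolite_library(8, lw_f1 = 2, lw_f2 = 0.3)
  cfg <- mixture_config(c(2, 3), spectra_per_type = 4, grid = grid, seed = 5)
  ds <- build_dataset(cfg, lib)
  expect_length(ds$spectra, 8)
  expect_equal(unique(ds$manifest$n_metab), c(2, 3))
  ds2 <- build_dataset(cfg, lib)
  expect_identical(lapply(ds$spectra, `[[`, "grid"),
                   lapply(ds2$spectra, `[[`, "grid"))
  expect_identical(ds$manifest, ds2$manifest)
  one <- build_dataset(mixture_config(1, 1, grid, seed = 2), lib)
  expect_length(one$spectra, 1)
  expect_error(build_dataset(mixture_config(99, 1, grid, seed = 2), lib),
               "library smaller")
})

test_that("metabolite libraries round-trip through YAML", {
  lib <- default_metabolite_library(4)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_metabolite_library(lib, tmp)
  back <- read_metabolite_library(tmp)
  expect_length(back, 4)
  expect_equal(back[[2]]$name, lib[[2]]$name)
  expect_equal(back[[2]]$conc_mean, lib[[2]]$conc_mean)
  expect_equal(back[[3]]$multiplets[[1]]$couplings,
               lib[[3]]$multiplets[[1]]$couplings)
})
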