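#' Grid (axis pair) constructors
#'
#' `jres_grid()` builds the F1/F2 axis pair of a simulation grid. The default
#' physical ranges are those of the simulated urine/plasma sets: F1 from
#' -39.1542 to 39.1542 Hz, F2 from -3.560 to 13.129 ppm. The full-scale grid
#' is 256 x 16384; `demo_grid()` keeps the same physical ranges on a reduced
#' 64 x 1024 raster suitable for desk-scale training and tests.
#'
#' @param n_f1,n_f2 pixel counts along F1 and F2.
#' @param f1_range,f2_range physical ranges (length-2 numerics).
#' @return list with elements `f1` and `f2`, both [jres_axis()].
#' @export
jres_grid <- function(n_f1 = 256, n_f2 = 16384,
                      f1_range = c(-39.1542, 39.1542),
                      f2_range = c(-3.560, 13.129)) {
  list(f1 = jres_axis(n_f1, f1_range[1], f1_range[2], "Hz"),
       f2 = jres_axis(n_f2, f2_range[1], f2_range[2], "ppm"))
}

#' @rdname jres_grid
#' @export
demo_grid <- function() jres_grid(64, 1024)

# evaluate code with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# normalized 1D lineshapes (unit integral over the physical coordinate)
gauss_profile <- function(x, centre, fwhm) {
  stats::dnorm(x, centre, fwhm / (2 * sqrt(2 * log(2))))
}
lorentz_profile <- function(x, centre, fwhm) {
  g <- fwhm / 2
  (g / pi) / ((x - centre)^2 + g^2)
}

#' Render a metabolite's J-Res signature onto a grid
#'
#' Sums, over all multiplets and their first-order components, a separable
#' 2D lineshape: Gaussian along F1 (centred at the component's J offset) and
#' Lorentzian along F2 (centred at the multiplet's chemical shift). Each
#' lineshape has unit integral in physical units, so the rendered grid total
#' times the pixel area approximates the total proton weight. Because the
#' component offsets negate pairwise and the F1 axis is symmetric, the output
#' is exactly symmetric under [flip_f1()].
#'
#' @param m a [jres_metabolite()].
#' @param grid axis pair from [jres_grid()].
#' @param observe_frequency MHz (default 600).
#' @return a [jres_spectrum()].
#' @export
render_metabolite <- function(m, grid = demo_grid(), observe_frequency = 600) {
  stopifnot(inherits(m, "jres_metabolite"))
  f1c <- axis_coords(grid$f1)
  f2c <- axis_coords(grid$f2)
  f1r <- range(grid$f1$start, grid$f1$end)
  f2r <- range(grid$f2$start, grid$f2$end)
  G <- matrix(0, grid$f1$n_points, grid$f2$n_points)
  for (mp in m$multiplets) {
    if (mp$delta < f2r[1] || mp$delta > f2r[2])
      stop(sprintf("metabolite '%s': multiplet at %.3f ppm outside F2 range",
                   m$name, mp$delta), call. = FALSE)
    comps <- multiplet_components(mp$couplings)
    if (max(abs(comps$offset)) + 3 * mp$lw_f1 > max(abs(f1r)))
      stop(sprintf(
        "metabolite '%s': multiplet at %.3f ppm has components outside F1 range",
        m$name, mp$delta), call. = FALSE)
    p2 <- lorentz_profile(f2c, mp$delta, mp$lw_f2)
    for (k in seq_len(nrow(comps))) {
      p1 <- gauss_profile(f1c, comps$offset[k], mp$lw_f1)
      G <- G + (mp$proton_weight * comps$intensity[k]) * outer(p1, p2)
    }
  }
  jres_spectrum(G, grid$f1, grid$f2, observe_frequency, label = m$name)
}

#' Draw a concentration for a metabolite
#'
#' Samples Normal(`conc_mean`, `conc_sd`) truncated below at zero by
#' resampling, so concentrations are always non-negative; `conc_sd = 0`
#' returns the mean exactly.
#'
#' @param m a [jres_metabolite()].
#' @return a single non-negative concentration.
#' @export
sample_concentration <- function(m) {
  if (m$conc_sd == 0) return(m$conc_mean)
  repeat {
    x <- stats::rnorm(1, m$conc_mean, m$conc_sd)
    if (x >= 0) return(x)
  }
}

#' Simulate a mixture spectrum
#'
#' Linear combination of the rendered signatures of the first `n_metab`
#' members of the library, weighted by concentrations (drawn with
#' [sample_concentration()] unless supplied). The mixture composition is
#' recorded in the `"mixture"` attribute of the result.
#'
#' @param library list of [jres_metabolite()].
#' @param n_metab how many (leading) library members to include.
#' @param grid axis pair from [jres_grid()].
#' @param concentrations optional explicit concentration vector (length
#'   `n_metab`); when given, no random draws are made.
#' @param observe_frequency MHz.
#' @param label spectrum label.
#' @return a [jres_spectrum()] with a `"mixture"` attribute
#'   (data.frame: name, concentration).
#' @export
simulate_mixture <- function(library, n_metab, grid = demo_grid(),
                             concentrations = NULL, observe_frequency = 600,
                             label = sprintf("mixture_%d", n_metab)) {
  if (n_metab < 1 || n_metab > length(library))
    stop("n_metab must be between 1 and the library size", call. = FALSE)
  members <- library[seq_len(n_metab)]
  if (is.null(concentrations))
    concentrations <- vapply(members, sample_concentration, numeric(1))
  stopifnot(length(concentrations) == n_metab, all(concentrations >= 0))
  G <- matrix(0, grid$f1$n_points, grid$f2$n_points)
  for (i in seq_len(n_metab)) {
    if (concentrations[i] == 0) next
    G <- G + concentrations[i] *
      render_metabolite(members[[i]], grid, observe_frequency)$grid
  }
  s <- jres_spectrum(G, grid$f1, grid$f2, observe_frequency, label = label)
  attr(s, "mixture") <- data.frame(
    name = vapply(members, `[[`, "", "name"),
    concentration = concentrations
  )
  s
}

#' Mixture dataset configuration
#'
#' Defaults mirror the simulated urine training set: five mixture types of
#' 6, 8, 15, 34 and 40 metabolites, 1000 spectra per type. The plasma-style
#' test set uses `metabolite_counts = c(1, 3, 6, 9, 12, 15)` with one
#' spectrum per type.
#'
#' @param metabolite_counts integer vector of mixture sizes.
#' @param spectra_per_type spectra per mixture type.
#' @param grid axis pair from [jres_grid()].
#' @param seed RNG seed making the dataset reproducible.
#' @return An object of class `jres_mixture_config`.
#' @export
mixture_config <- function(metabolite_counts = c(6, 8, 15, 34, 40),
                           spectra_per_type = 1000,
                           grid = jres_grid(), seed = 1) {
  if (any(metabolite_counts < 1))
    stop("metabolite counts must be >= 1", call. = FALSE)
  structure(list(metabolite_counts = as.integer(metabolite_counts),
                 spectra_per_type = as.integer(spectra_per_type),
                 grid = grid, seed = as.integer(seed)),
            class = "jres_mixture_config")
}

#' Build a mixture dataset
#'
#' Generates `length(metabolite_counts) * spectra_per_type` HR spectra with
#' freshly drawn concentrations, plus a manifest recording every draw. Two
#' calls with the same config and library produce identical grids and
#' manifests.
#'
#' @param cfg a [mixture_config()].
#' @param library list of [jres_metabolite()]; must cover `max(counts)`.
#' @return An object of class `jres_dataset`: list with `spectra` (list of
#'   [jres_spectrum()]) and `manifest` (data.frame: spectrum, n_metab,
#'   metabolite, concentration).
#' @export
build_dataset <- function(cfg, library = default_metabolite_library()) {
  stopifnot(inherits(cfg, "jres_mixture_config"))
  if (max(cfg$metabolite_counts) > length(library))
    stop("library smaller than the largest mixture size", call. = FALSE)
  with_seed(cfg$seed, {
    spectra <- list()
    rows <- list()
    idx <- 0L
    for (n_metab in cfg$metabolite_counts) {
      for (rep in seq_len(cfg$spectra_per_type)) {
        idx <- idx + 1L
        s <- simulate_mixture(library, n_metab, cfg$grid,
                              label = sprintf("mix%02d_rep%04d", n_metab, rep))
        spectra[[idx]] <- s
        mix <- attr(s, "mixture")
        rows[[idx]] <- data.frame(spectrum = idx, n_metab = n_metab,
                                  metabolite = mix$name,
                                  concentration = mix$concentration)
      }
    }
    structure(list(spectra = spectra, manifest = do.call(rbind, rows)),
              class = "jres_dataset")
  })
}

#' Packaged synthetic metabolite library
#'
#' A reproducible library of parametric pure-compound signatures: each
#' metabolite has 1-3 multiplets with chemical shifts in 0.5-9.5 ppm, up to
#' three couplings of 2-18 Hz per multiplet, proton weights of 1-3, and
#' log-uniform concentration means with a 20% relative standard deviation.
#' These are synthetic stand-ins that preserve the statistical character of
#' a real pure-compound library (multiplet structure, crowding, dynamic
#' range), not real compound assignments.
#'
#' @param n number of metabolites.
#' @param seed seed fixing the library.
#' @param lw_f1,lw_f2 linewidths passed to every multiplet (Hz, ppm).
#' @return list of [jres_metabolite()].
#' @export
default_metabolite_library <- function(n = 40, seed = 914,
                                       lw_f1 = 0.4, lw_f2 = 0.002) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      n_mp <- sample(1:3, 1)
      mps <- lapply(seq_len(n_mp), function(j) {
        n_j <- sample(0:3, 1, prob = c(0.2, 0.4, 0.3, 0.1))
        jres_multiplet(
          delta = stats::runif(1, 0.5, 9.5),
          couplings = if (n_j > 0) stats::runif(n_j, 2, 18) else numeric(),
          proton_weight = sample(1:3, 1),
          lw_f1 = lw_f1, lw_f2 = lw_f2
        )
      })
      cm <- 10^stats::runif(1, -1, 1)
      jres_metabolite(sprintf("synthetic_metabolite_%02d", i), mps,
                      conc_mean = cm, conc_sd = 0.2 * cm)
    })
  })
}

#' Read/write a metabolite library as YAML
#'
#' @param library list of [jres_metabolite()].
#' @param path YAML file path.
#' @return `read_metabolite_library` returns the library;
#'   `write_metabolite_library` returns `path` invisibly.
#' @export
write_metabolite_library <- function(library, path) {
  obj <- lapply(library, function(m) {
    list(name = m$name, conc_mean = m$conc_mean, conc_sd = m$conc_sd,
         multiplets = lapply(m$multiplets, function(mp) {
           list(delta = mp$delta, couplings = as.list(mp$couplings),
                proton_weight = mp$proton_weight,
                lw_f1 = mp$lw_f1, lw_f2 = mp$lw_f2)
         }))
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_metabolite_library
#' @export
read_metabolite_library <- function(path) {
  obj <- yaml::read_yaml(path)
  lapply(obj, function(m) {
    jres_metabolite(m$name,
                    lapply(m$multiplets, function(mp) {
                      jres_multiplet(mp$delta, unlist(mp$couplings),
                                     mp$proton_weight, mp$lw_f1, mp$lw_f2)
                    }),
                    conc_mean = m$conc_mean, conc_sd = m$conc_sd)
  })
}
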