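#' Multiplet description
#'
#' A first-order multiplet of a proton group: chemical shift centre, scalar
#' couplings and relative integral. In a J-Res spectrum the multiplet's
#' components spread along F1 at offsets that are sums of +/- J/2 over the
#' couplings, so the pattern is symmetric about J = 0 by construction.
#'
#' @param delta chemical shift centre (ppm).
#' @param couplings numeric vector of scalar coupling constants (Hz), all
#'   >= 0; empty for a singlet.
#' @param proton_weight relative integral (> 0), e.g. number of protons.
#' @param lw_f1 linewidth (FWHM) along F1 in Hz.
#' @param lw_f2 linewidth (FWHM) along F2 in ppm.
#' @return An object of class `jres_multiplet`.
#' @export
jres_multiplet <- function(delta, couplings = numeric(), proton_weight = 1,
                           lw_f1 = 0.4, lw_f2 = 0.002) {
  couplings <- as.numeric(couplings)
  if (length(couplings) && (any(!is.finite(couplings)) || any(couplings < 0)))
    stop("couplings must be finite and >= 0", call. = FALSE)
  if (proton_weight <= 0) stop("proton_weight must be > 0", call. = FALSE)
  if (lw_f1 <= 0 || lw_f2 <= 0) stop("linewidths must be > 0", call. = FALSE)
  structure(list(delta = delta, couplings = couplings,
                 proton_weight = proton_weight, lw_f1 = lw_f1, lw_f2 = lw_f2),
            class = "jres_multiplet")
}

#' Metabolite description
#'
#' A named set of multiplets plus the parameters of the normal distribution
#' its concentration is drawn from when simulating mixtures.
#'
#' @param name identifier.
#' @param multiplets list of [jres_multiplet()].
#' @param conc_mean concentration mean (> 0, arbitrary units).
#' @param conc_sd concentration standard deviation (>= 0).
#' @return An object of class `jres_metabolite`.
#' @export
jres_metabolite <- function(name, multiplets, conc_mean = 1, conc_sd = 0) {
  if (conc_mean <= 0) stop("conc_mean must be > 0", call. = FALSE)
  if (conc_sd < 0) stop("conc_sd must be >= 0", call. = FALSE)
  if (!all(vapply(multiplets, inherits, TRUE, "jres_multiplet")))
    stop("multiplets must all be jres_multiplet objects", call. = FALSE)
  structure(list(name = name, multiplets = multiplets,
                 conc_mean = conc_mean, conc_sd = conc_sd),
            class = "jres_metabolite")
}

#' First-order multiplet components
#'
#' Expands a coupling list into F1 component offsets and relative
#' intensities: each coupling J splits every existing line into two at
#' +/- J/2 with half the intensity, and coincident offsets are merged (e.g.
#' two equal couplings give the 1:2:1 triplet). The result is symmetric
#' about 0 and its intensities sum to 1.
#'
#' @param couplings numeric vector of coupling constants (Hz), all >= 0.
#' @param merge_tol offsets closer than this (Hz) are merged.
#' @return data.frame with columns `offset` (Hz, ascending) and `intensity`.
#' @examples
#' multiplet_components(c(7, 7)) # 1:2:1 triplet at -7, 0, +7
#' @export
multiplet_components <- function(couplings, merge_tol = 1e-6) {
  couplings <- as.numeric(couplings)
  if (any(!is.finite(couplings)) || any(couplings < 0))
    stop("couplings must be finite and >= 0", call. = FALSE)
  off <- 0
  int <- 1
  for (J in couplings) {
    off <- c(off - J / 2, off + J / 2)
    int <- c(int, int) / 2
  }
  ord <- order(off)
  off <- off[ord]
  int <- int[ord]
  grp <- cumsum(c(1, diff(off) > merge_tol))
  data.frame(offset = as.numeric(tapply(off, grp, mean)),
             intensity = as.numeric(tapply(int, grp, sum)))
}
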