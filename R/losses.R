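#' Symmetric loss of a J-Res spectrum
#'
#' Measures how far a spectrum departs from the mirror symmetry about
#' J = 0 that every ideal J-Res spectrum obeys. For each column i of the set
#' P of columns containing nonzero (strictly positive) pixels, the upper
#' half and the mirrored lower half are log-transformed (so the loss is not
#' dominated by the most intense peaks) and compared with the Pearson
#' correlation r_i; the loss is
#'
#'   L_sym = 1 - (1/n) * sum_{i in P} r_i,   n = |P|,
#'
#' which is 0 for a perfectly symmetric spectrum and at most 2 (all columns
#' exactly anticorrelated). Columns where either log-half has zero variance
#' are excluded (r undefined) unless both halves are identical constants, in
#' which case the column contributes r = 1; if no column qualifies the loss
#' is 0.
#'
#' The log transform is `log(max(x, 0) + eps)` with
#' `eps = eps_frac * max(grid)`.
#'
#' @param s a [jres_spectrum()] or intensity matrix with an even row count.
#' @param eps_frac log-offset as a fraction of the global maximum.
#' @param grad if `TRUE`, also return the gradient of the loss with respect
#'   to the grid (used by the training loop; positive-intensity pixels only,
#'   eps treated as constant).
#' @return the scalar loss, or (with `grad = TRUE`) a list
#'   `list(loss, grad, n)`.
#' @export
symmetric_loss <- function(s, eps_frac = 1e-6, grad = FALSE) {
  g <- if (inherits(s, "jres_spectrum")) s$grid else as.matrix(s)
  n1 <- nrow(g)
  if (n1 %% 2 != 0) stop("symmetric_loss needs an even number of rows",
                         call. = FALSE)
  half <- n1 %/% 2
  gm <- max(g)
  zero_out <- if (grad) list(loss = 0, grad = matrix(0, n1, ncol(g)), n = 0L)
              else 0
  if (gm <= 0) return(zero_out)
  gc <- pmax(g, 0)
  eps <- eps_frac * gm
  inP <- colSums(gc > 0) > 0
  if (!any(inP)) return(zero_out)
  up_rows <- seq_len(half)
  lo_rows <- rev(half + seq_len(half))      # mirrored lower half
  u <- log(gc[up_rows, inP, drop = FALSE] + eps)
  l <- log(gc[lo_rows, inP, drop = FALSE] + eps)
  uc <- sweep(u, 2, colMeans(u))
  lc <- sweep(l, 2, colMeans(l))
  du <- colSums(uc^2)
  dl <- colSums(lc^2)
  num <- colSums(uc * lc)
  ok <- du > 0 & dl > 0
  const_eq <- du == 0 & dl == 0 & colSums(abs(u - l)) == 0
  r <- rep(NA_real_, ncol(u))
  r[ok] <- num[ok] / sqrt(du[ok] * dl[ok])
  r[const_eq] <- 1
  keep <- ok | const_eq
  n <- sum(keep)
  if (n == 0) return(zero_out)
  loss <- 1 - mean(r[keep])
  if (!grad) return(loss)

  G <- matrix(0, n1, ncol(g))
  cols <- which(inP)[keep & ok]             # constant columns have zero grad
  kidx <- which(keep & ok)
  if (length(kidx)) {
    rk <- r[kidx]
    duk <- du[kidx]; dlk <- dl[kidx]
    sul <- sqrt(duk * dlk)
    # dr/du and dr/dl for the centred log vectors, per column
    dr_du <- sweep(lc[, kidx, drop = FALSE], 2, sul, "/") -
      sweep(uc[, kidx, drop = FALSE], 2, rk / duk, "*")
    dr_dl <- sweep(uc[, kidx, drop = FALSE], 2, sul, "/") -
      sweep(lc[, kidx, drop = FALSE], 2, rk / dlk, "*")
    # chain through the clipped log transform
    xu <- gc[up_rows, inP, drop = FALSE][, kidx, drop = FALSE]
    xl <- gc[lo_rows, inP, drop = FALSE][, kidx, drop = FALSE]
    gu <- -(1 / n) * dr_du / (xu + eps) * (xu > 0)
    gl <- -(1 / n) * dr_dl / (xl + eps) * (xl > 0)
    G[up_rows, cols] <- gu
    G[lo_rows, cols] <- gl
  }
  list(loss = loss, grad = G, n = n)
}

#' Mean absolute (L1) pixel loss
#'
#' @param pred,target equal-dimension [jres_spectrum()]s or matrices.
#' @param grad if `TRUE`, also return the gradient with respect to `pred`.
#' @return scalar loss, or `list(loss, grad)`.
#' @export
pixel_loss <- function(pred, target, grad = FALSE) {
  p <- if (inherits(pred, "jres_spectrum")) pred$grid else as.matrix(pred)
  t <- if (inherits(target, "jres_spectrum")) target$grid else as.matrix(target)
  if (!identical(dim(p), dim(t)))
    stop("pixel_loss: dimension mismatch", call. = FALSE)
  d <- p - t
  loss <- mean(abs(d))
  if (!grad) return(loss)
  list(loss = loss, grad = sign(d) / length(d))
}

# numerically stable softplus and sigmoid
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Non-saturating adversarial objectives
#'
#' Given the discriminator's per-pixel realness logits on real and generated
#' (fake) inputs, returns the standard non-saturating GAN terms:
#' the generator term `mean(softplus(-D(fake)))` (low when fakes are judged
#' real) and the discriminator term
#' `mean(softplus(-D(real))) + mean(softplus(D(fake)))`. At the decision
#' midpoint (all logits 0) the terms are `log 2` and `2 log 2`.
#'
#' @param disc_out_real,disc_out_fake numeric arrays of logits.
#' @return list with elements `generator` and `discriminator`.
#' @export
gan_losses <- function(disc_out_real, disc_out_fake) {
  r <- as.numeric(disc_out_real)
  f <- as.numeric(disc_out_fake)
  if (!all(is.finite(r)) || !all(is.finite(f)))
    stop("discriminator outputs must be finite", call. = FALSE)
  list(generator = mean(softplus(-f)),
       discriminator = mean(softplus(-r)) + mean(softplus(f)))
}
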