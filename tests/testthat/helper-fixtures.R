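# shared fixtures, built in code at test time

# the full-scale F2 axis (chemical shift) and a spectrum-sized F1 axis
paper_f2_axis <- function() jres_axis(16384, -3.560, 13.129, "ppm")

# a tiny spectrum with an arbitrary grid for container round-trips
toy_spectrum <- function(n1 = 4, n2 = 8, seed = 1) {
  set.seed(seed)
  jres_spectrum(matrix(rnorm(n1 * n2), n1, n2),
                jres_axis(n1, -40, 40, "Hz"),
                jres_axis(n2, -3.56, 13.129, "ppm"),
                label = "toy")
}

# a grid with isolated single-pixel peaks at given 0-based (row, col)
peaks_grid <- function(n1, n2, at, heights = 1) {
  g <- matrix(0, n1, n2)
  heights <- rep_len(heights, nrow(at))
  for (i in seq_len(nrow(at))) g[at[i, 1] + 1, at[i, 2] + 1] <- heights[i]
  jres_spectrum(g, jres_axis(n1, -40, 40, "Hz"),
                jres_axis(n2, -3.56, 13.129, "ppm"))
}

# brute-force pair-formation oracle: all-pairs distances, k nearest per
# peak, union of unordered pairs, distance cutoff
form_pairs_oracle <- function(peaks, k = 3, max_dist_px = 30) {
  n <- nrow(peaks)
  seen <- character()
  out <- list()
  for (i in seq_len(n)) {
    d <- sqrt((peaks$row - peaks$row[i])^2 + (peaks$col - peaks$col[i])^2)
    ord <- order(d, peaks$row, peaks$col)
    ord <- ord[ord != i]
    for (j in ord[seq_len(min(k, n - 1))]) {
      a <- min(i, j); b <- max(i, j)
      key <- paste(a, b)
      if (key %in% seen) next
      seen <- c(seen, key)
      dd <- sqrt((peaks$row[a] - peaks$row[b])^2 +
                   (peaks$col[a] - peaks$col[b])^2)
      if (dd > 0 && dd <= max_dist_px)
        out[[length(out) + 1]] <- c(a = a, b = b, d = dd)
    }
  }
  if (!length(out)) return(data.frame(a = integer(), b = integer(),
                                      d = numeric()))
  m <- do.call(rbind, out)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(a = m[, 1], b = m[, 2], d = m[, 3])
}

# canonical unordered-pair key set for comparing pair tables
pair_keys <- function(df_rowcol) {
  apply(df_rowcol, 1, function(r) {
    a <- r[1:2]; b <- r[3:4]
    if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) { tmp <- a; a <- b; b <- tmp }
    paste(a[1], a[2], b[1], b[2])
  })
}

# 2^k sign-enumeration oracle for multiplet components
multiplet_components_oracle <- function(couplings, tol = 1e-6) {
  if (!length(couplings))
    return(data.frame(offset = 0, intensity = 1))
  signs <- as.matrix(expand.grid(rep(list(c(-0.5, 0.5)), length(couplings))))
  off <- as.numeric(signs %*% couplings)
  ord <- order(off)
  off <- off[ord]
  grp <- cumsum(c(1, diff(off) > tol))
  data.frame(offset = as.numeric(tapply(off, grp, mean)),
             intensity = as.numeric(tapply(rep(1 / nrow(signs),
                                               length(off)), grp, sum)))
}
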