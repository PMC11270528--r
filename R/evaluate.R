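#' Pick 2D peaks
#'
#' 8-neighbour local maxima at or above a height threshold expressed as a
#' fraction of the global maximum, returned sorted by height (descending),
#' ties broken by (row, col). Coordinates are 0-based. Plateaus of equal
#' pixels are reported once, at their first pixel in (row, col) scan order:
#' a J-Res peak sitting exactly on the J = 0 line spans the two mirror rows
#' with equal intensity, so a strictly-greater-than-all-neighbours rule
#' would miss every such peak.
#'
#' @param s a [jres_spectrum()].
#' @param threshold_frac detection threshold in (0, 1), as a fraction of the
#'   global maximum intensity.
#' @return data.frame with columns `row`, `col`, `height`.
#' @export
pick_peaks <- function(s, threshold_frac = 0.01) {
  stopifnot(inherits(s, "jres_spectrum"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must be in (0, 1)", call. = FALSE)
  g <- s$grid
  gmax <- max(g)
  empty <- data.frame(row = integer(), col = integer(), height = numeric())
  if (gmax <= 0) return(empty)
  n1 <- nrow(g); n2 <- ncol(g)
  gp <- matrix(-Inf, n1 + 2L, n2 + 2L)
  gp[1L + seq_len(n1), 1L + seq_len(n2)] <- g
  ctr <- gp[1L + seq_len(n1), 1L + seq_len(n2)]
  is_max <- ctr >= threshold_frac * gmax
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- gp[1L + dr + seq_len(n1), 1L + dc + seq_len(n2)]
    # strictly above neighbours earlier in scan order, at least equal to
    # later ones: each plateau yields exactly one peak
    is_max <- is_max & if (dr < 0 || (dr == 0 && dc < 0)) ctr > nb
                       else ctr >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  out <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                    height = g[idx])
  out <- out[order(-out$height, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Form candidate adjacent peak pairs
#'
#' For every peak the `k` nearest other peaks are recorded as candidate
#' pairs; the union is deduplicated (unordered pairs) and pairs farther
#' apart than `max_dist_px` pixels (Euclidean) are excluded. Nearest-
#' neighbour ties are broken by (distance, row, col) of the neighbour.
#'
#' @param peaks data.frame from [pick_peaks()].
#' @param k neighbours per peak (default 3).
#' @param max_dist_px distance cutoff in pixels (default 30).
#' @return data.frame with the two peaks' coordinates/heights and
#'   `distance_px`, sorted by (a_row, a_col, b_row, b_col).
#' @export
form_pairs <- function(peaks, k = 3, max_dist_px = 30) {
  n <- nrow(peaks)
  empty <- data.frame(a_row = integer(), a_col = integer(),
                      a_height = numeric(), b_row = integer(),
                      b_col = integer(), b_height = numeric(),
                      distance_px = numeric())
  if (n < 2) return(empty)
  d <- as.matrix(stats::dist(cbind(peaks$row, peaks$col)))
  sel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], peaks$row[-i], peaks$col[-i])
    nb <- (seq_len(n)[-i])[ord[seq_len(min(k, n - 1))]]
    sel[i, nb] <- TRUE
  }
  sel <- sel | t(sel)
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  keep <- d[idx] <= max_dist_px & d[idx] > 0
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0) return(empty)
  out <- data.frame(a_row = peaks$row[idx[, 1]], a_col = peaks$col[idx[, 1]],
                    a_height = peaks$height[idx[, 1]],
                    b_row = peaks$row[idx[, 2]], b_col = peaks$col[idx[, 2]],
                    b_height = peaks$height[idx[, 2]],
                    distance_px = d[idx])
  out <- out[order(out$a_row, out$a_col, out$b_row, out$b_col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-locate a peak in another spectrum
#'
#' Maps a peak position into a (possibly differently sized) spectrum by the
#' per-axis grid-size ratio, then searches the `+/- window_px` box around
#' the mapped position: the highest strict local maximum inside the box is
#' returned, or, if the box contains none, its maximum-intensity pixel
#' (flagged with `matched = FALSE`). Boxes extending past the grid are
#' clipped.
#'
#' @param p list or one-row data.frame with 0-based `row`, `col`.
#' @param s target [jres_spectrum()].
#' @param window_px half-width of the search box (default 3).
#' @param from_dim c(rows, cols) of the grid `p` was picked on; defaults to
#'   `dim(s)` (no scaling).
#' @return list with `row`, `col`, `height`, `matched`.
#' @export
match_position <- function(p, s, window_px = 3, from_dim = dim(s$grid)) {
  g <- s$grid
  n1 <- nrow(g); n2 <- ncol(g)
  r0 <- round(p$row * n1 / from_dim[1])
  c0 <- round(p$col * n2 / from_dim[2])
  r0 <- min(max(r0, 0), n1 - 1)
  c0 <- min(max(c0, 0), n2 - 1)
  rr <- max(0, r0 - window_px):min(n1 - 1, r0 + window_px)
  cc <- max(0, c0 - window_px):min(n2 - 1, c0 + window_px)
  # local maxima of the full grid restricted to the box
  gp <- matrix(-Inf, n1 + 2L, n2 + 2L)
  gp[1L + seq_len(n1), 1L + seq_len(n2)] <- g
  box <- g[rr + 1L, cc + 1L, drop = FALSE]
  is_max <- matrix(TRUE, length(rr), length(cc))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (box > gp[rr + 2L + dr, cc + 2L + dc, drop = FALSE])
  }
  hit <- which(is_max, arr.ind = TRUE)
  if (nrow(hit)) {
    h <- box[hit]
    best <- hit[order(-h, hit[, 1], hit[, 2])[1], ]
    list(row = rr[best[1]], col = cc[best[2]], height = box[best[1], best[2]],
         matched = TRUE)
  } else {
    best <- which(box == max(box), arr.ind = TRUE)[1, ]
    list(row = rr[best[1]], col = cc[best[2]], height = box[best[1], best[2]],
         matched = FALSE)
  }
}

# bilinear interpolation at 0-based fractional coordinates
bilinear_at <- function(g, r, c) {
  n1 <- nrow(g); n2 <- ncol(g)
  r <- pmin(pmax(r, 0), n1 - 1)
  c <- pmin(pmax(c, 0), n2 - 1)
  r0 <- pmin(floor(r), n1 - 2); c0 <- pmin(floor(c), n2 - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i <- function(a, b) g[cbind(a + 1L, b + 1L)]
  (1 - fr) * (1 - fc) * i(r0, c0) + fr * (1 - fc) * i(r0 + 1, c0) +
    (1 - fr) * fc * i(r0, c0 + 1) + fr * fc * i(r0 + 1, c0 + 1)
}

#' Valley-floor height between two peaks
#'
#' Minimum intensity along the straight line connecting two peak positions
#' (endpoints included), sampled at unit steps with bilinear interpolation;
#' this generalizes row, column and diagonal profiles.
#'
#' @param s a [jres_spectrum()].
#' @param a,b lists/rows with 0-based `row`, `col` (must differ).
#' @return the minimum interpolated intensity along the profile.
#' @export
valley_height <- function(s, a, b) {
  if (a$row == b$row && a$col == b$col)
    stop("valley_height needs two distinct positions", call. = FALSE)
  d <- sqrt((a$row - b$row)^2 + (a$col - b$col)^2)
  ts <- seq(0, 1, length.out = max(2L, ceiling(d) + 1L))
  min(bilinear_at(s$grid, a$row + ts * (b$row - a$row),
                  a$col + ts * (b$col - a$col)))
}

#' Resolvability score of a peak pair
#'
#' Depth of the valley between two adjacent peaks relative to their heights:
#' `1 - 2 * h_v / (h_i + h_j)` (mean-height normalization), clipped to
#' \[0, 1\]. The score is 1 for a fully resolved pair (valley floor at
#' baseline) and 0 for fully merged peaks (valley as high as the peaks).
#' `method = "min"` uses `1 - h_v / min(h_i, h_j)` instead.
#'
#' @param h_i,h_j heights of the two peaks (> 0).
#' @param h_v valley-floor height (>= 0).
#' @param method normalization: `"mean"` (default) or `"min"`.
#' @return score in \[0, 1\] (vectorized).
#' @export
resolvability <- function(h_i, h_j, h_v, method = c("mean", "min")) {
  method <- match.arg(method)
  if (any(h_i <= 0) || any(h_j <= 0))
    stop("peak heights must be positive", call. = FALSE)
  if (any(h_v < 0)) stop("valley height must be non-negative", call. = FALSE)
  raw <- switch(method,
                mean = 1 - 2 * h_v / (h_i + h_j),
                min = 1 - h_v / pmin(h_i, h_j))
  pmin(pmax(raw, 0), 1)
}

#' Resolvability category
#'
#' Bins a score into "poorly" (\[0, 0.2)), "partially" (\[0.2, 0.6)) or
#' "well" (\[0.6, 1\]) resolved; bins are closed on the left, and 1 belongs
#' to "well".
#'
#' @param score numeric scores in \[0, 1\].
#' @return character vector.
#' @export
resolvability_category <- function(score) {
  out <- rep(NA_character_, length(score))
  out[score >= 0 & score < 0.2] <- "poorly resolved"
  out[score >= 0.2 & score < 0.6] <- "partially resolved"
  out[score >= 0.6] <- "well resolved"
  out
}

#' Score peak pairs across HR, LR and SR spectra
#'
#' HR-anchored scoring: for each HR peak pair, the two peak positions are
#' re-located in each spectrum with [match_position()] (coordinates scaled
#' by the grid-size ratio, so the half-size LR grid is handled
#' transparently), the valley floor between the matched positions is
#' measured, and the resolvability score and category are computed. Pairs
#' whose peaks could not be matched to a local maximum, or that collapse to
#' a single position, are flagged (`matched_*`), never dropped.
#'
#' @param hr,lr,sr [jres_spectrum()]s (LR may have half-size dims).
#' @param pairs data.frame from [form_pairs()] run on `hr`.
#' @param window_px search half-width for [match_position()].
#' @param method resolvability normalization (see [resolvability()]).
#' @return data.frame, one row per pair: pair id, HR coordinates and
#'   distance, then `h_i/h_j/h_v/score/category/matched` per resolution
#'   (suffixes `_hr`, `_lr`, `_sr`).
#' @export
score_pairs <- function(hr, lr, sr, pairs, window_px = 3,
                        method = c("mean", "min")) {
  method <- match.arg(method)
  specs <- list(hr = hr, lr = lr, sr = sr)
  n <- nrow(pairs)
  out <- data.frame(pair = seq_len(n),
                    a_row = pairs$a_row, a_col = pairs$a_col,
                    b_row = pairs$b_row, b_col = pairs$b_col,
                    distance_px = pairs$distance_px)
  from_dim <- dim(hr$grid)
  for (nm in names(specs)) {
    s <- specs[[nm]]
    hi <- hj <- hv <- sc <- rep(NA_real_, n)
    ok <- rep(FALSE, n)
    for (i in seq_len(n)) {
      ma <- match_position(list(row = pairs$a_row[i], col = pairs$a_col[i]),
                           s, window_px, from_dim)
      mb <- match_position(list(row = pairs$b_row[i], col = pairs$b_col[i]),
                           s, window_px, from_dim)
      merged <- ma$row == mb$row && ma$col == mb$col
      hi[i] <- ma$height; hj[i] <- mb$height
      if (merged) {
        hv[i] <- ma$height
      } else {
        hv[i] <- valley_height(s, ma, mb)
      }
      if (hi[i] > 0 && hj[i] > 0) {
        sc[i] <- resolvability(hi[i], hj[i], max(hv[i], 0), method)
        ok[i] <- ma$matched && mb$matched && !merged
      }
    }
    out[[paste0("h_i_", nm)]] <- hi
    out[[paste0("h_j_", nm)]] <- hj
    out[[paste0("h_v_", nm)]] <- hv
    out[[paste0("score_", nm)]] <- sc
    out[[paste0("category_", nm)]] <- resolvability_category(sc)
    out[[paste0("matched_", nm)]] <- ok
  }
  out
}

#' Summarize resolvability records
#'
#' Improvement fractions (SR over LR), the Pearson correlation between HR
#' and SR scores, and per-distance-bin (10-pixel bins) score summaries for
#' each resolution.
#'
#' @param records data.frame from [score_pairs()].
#' @param bin_px distance bin width in pixels.
#' @return list of class `jres_eval_summary`: `n_pairs`,
#'   `frac_sr_ge_lr`, `frac_sr_gt_lr`, `cor_hr_sr` (NA when undefined, with
#'   `cor_defined` flag), and `bins` (data.frame: bin, resolution, n, mean,
#'   median).
#' @export
summarize_scores <- function(records, bin_px = 10) {
  if (nrow(records) < 2)
    stop("need at least 2 records to summarize", call. = FALSE)
  use <- is.finite(records$score_lr) & is.finite(records$score_sr)
  frac_ge <- mean(records$score_sr[use] >= records$score_lr[use])
  frac_gt <- mean(records$score_sr[use] > records$score_lr[use])
  usec <- is.finite(records$score_hr) & is.finite(records$score_sr)
  cor_ok <- sum(usec) >= 2 && stats::sd(records$score_hr[usec]) > 0 &&
    stats::sd(records$score_sr[usec]) > 0
  rho <- if (cor_ok) stats::cor(records$score_hr[usec],
                                records$score_sr[usec]) else NA_real_
  bin <- floor(records$distance_px / bin_px) * bin_px
  bins <- do.call(rbind, lapply(c("hr", "lr", "sr"), function(nm) {
    sc <- records[[paste0("score_", nm)]]
    ok <- is.finite(sc)
    agg_m <- tapply(sc[ok], bin[ok], mean)
    agg_md <- tapply(sc[ok], bin[ok], stats::median)
    agg_n <- tapply(sc[ok], bin[ok], length)
    data.frame(bin_lo = as.numeric(names(agg_m)),
               bin_hi = as.numeric(names(agg_m)) + bin_px,
               resolution = nm, n = as.integer(agg_n),
               mean = as.numeric(agg_m), median = as.numeric(agg_md))
  }))
  rownames(bins) <- NULL
  structure(list(n_pairs = nrow(records), n_scored = sum(use),
                 frac_sr_ge_lr = frac_ge, frac_sr_gt_lr = frac_gt,
                 cor_hr_sr = rho, cor_defined = cor_ok, bins = bins),
            class = "jres_eval_summary")
}

#' @export
print.jres_eval_summary <- function(x, ...) {
  cat(sprintf("<jres_eval_summary> %d pairs (%d scored)\n", x$n_pairs,
              x$n_scored))
  cat(sprintf("  SR >= LR: %.1f%% | SR > LR: %.1f%% | cor(HR, SR): %s\n",
              100 * x$frac_sr_ge_lr, 100 * x$frac_sr_gt_lr,
              if (x$cor_defined) sprintf("%.3f", x$cor_hr_sr) else "undefined"))
  invisible(x)
}

# greedy one-to-one matching of detected peaks to truth peaks: candidate
# (detected, truth) pairs within tol are assigned in ascending distance order
greedy_match_count <- function(det, truth, tol_px) {
  if (nrow(det) == 0 || nrow(truth) == 0) return(0L)
  dr <- outer(det$row, truth$row, "-")
  dc <- outer(det$col, truth$col, "-")
  dd <- sqrt(dr^2 + dc^2)
  cand <- which(dd <= tol_px, arr.ind = TRUE)
  if (nrow(cand) == 0) return(0L)
  cand <- cand[order(dd[cand]), , drop = FALSE]
  used_d <- logical(nrow(det)); used_t <- logical(nrow(truth))
  m <- 0L
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1]; b <- cand[i, 2]
    if (!used_d[a] && !used_t[b]) {
      used_d[a] <- used_t[b] <- TRUE
      m <- m + 1L
    }
  }
  m
}

#' Reliability analysis against higher-resolution ground truth
#'
#' Takes a higher-resolution spectrum (`truth`, e.g. an HHR acquisition or
#' the simulation ground truth) as the reference for which peaks really
#' exist. Truth peaks are detected at `truth_threshold` (default 0.5% of
#' max); LR and SR peaks are detected at each of `thresholds`, scaled into
#' truth-grid coordinates, and matched one-to-one to truth peaks greedily by
#' ascending distance within `tol_px` pixels. For each threshold the table
#' reports detected and truth-matched counts and the fraction of the
#' additional SR peaks (beyond the LR count) that are truth-matched.
#'
#' @param lr,sr [jres_spectrum()]s to assess (any grid size; coordinates are
#'   rescaled to the truth grid).
#' @param truth ground-truth [jres_spectrum()], at least as large as `sr`.
#' @param thresholds detection thresholds for LR/SR (fractions of max).
#' @param truth_threshold detection threshold for the truth spectrum.
#' @param tol_px matching tolerance in truth-grid pixels (default 2).
#' @return data.frame of class `jres_reliability`: `threshold`, `n_lr`,
#'   `n_sr`, `matched_lr`, `matched_sr`, `frac_gained_matched` (NA when SR
#'   detects no more peaks than LR).
#' @export
reliability <- function(lr, sr, truth, thresholds = c(0.01, 0.05, 0.10),
                        truth_threshold = 0.005, tol_px = 2) {
  td <- dim(truth$grid)
  truth_peaks <- pick_peaks(truth, truth_threshold)
  scale_to_truth <- function(pk, s) {
    if (nrow(pk)) {
      pk$row <- pk$row * td[1] / nrow(s$grid)
      pk$col <- pk$col * td[2] / ncol(s$grid)
    }
    pk
  }
  rows <- lapply(thresholds, function(th) {
    plr <- scale_to_truth(pick_peaks(lr, th), lr)
    psr <- scale_to_truth(pick_peaks(sr, th), sr)
    mlr <- greedy_match_count(plr, truth_peaks, tol_px)
    msr <- greedy_match_count(psr, truth_peaks, tol_px)
    gained <- nrow(psr) - nrow(plr)
    frac <- if (gained > 0) {
      min(max((msr - mlr) / gained, 0), 1)
    } else NA_real_
    data.frame(threshold = th, n_lr = nrow(plr), n_sr = nrow(psr),
               matched_lr = mlr, matched_sr = msr,
               frac_gained_matched = frac)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("jres_reliability", "data.frame")
  out
}
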