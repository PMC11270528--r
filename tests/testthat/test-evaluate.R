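test_that("peak picking finds strict local maxima above threshold", {
  m <- jres_metabolite("s", list(jres_multiplet(5, lw_f1 = 1.5,
                                                lw_f2 = 0.05)))
  s <- render_metabolite(m, demo_grid())
  pk <- pick_peaks(s, 0.01)
  expect_equal(nrow(pk), 1)
  # the singlet centre: J = 0 straddles rows 31/32, shift 5 ppm
  expect_true(pk$row %in% c(31, 32))
  expect_equal(pk$col, which.max(s$grid[pk$row + 1, ]) - 1)
  # two equal maxima: both returned, ordered by (row, col)
  tw <- peaks_grid(16, 16, rbind(c(4, 8), c(10, 3)), heights = c(1, 1))
  pk2 <- pick_peaks(tw, 0.5)
  expect_equal(pk2$row, c(4, 10))
  expect_equal(pk2$col, c(8, 3))
  # all-zero spectrum and invalid thresholds
  z <- peaks_grid(8, 8, matrix(numeric(0), 0, 2))
  expect_equal(nrow(pick_peaks(z, 0.1)), 0)
  expect_error(pick_peaks(tw, 0), "threshold")
  expect_error(pick_peaks(tw, 1), "threshold")
})

test_that("pair formation applies the 3-NN and 30-pixel rules", {
  two <- data.frame(row = c(5, 5), col = c(0, 10), height = c(1, 1))
  expect_equal(nrow(form_pairs(two)), 1)
  far <- data.frame(row = c(0, 0), col = c(0, 31), height = c(1, 1))
  expect_equal(nrow(form_pairs(far, max_dist_px = 30)), 0)
  exact <- data.frame(row = c(0, 0), col = c(0, 30), height = c(1, 1))
  expect_equal(nrow(form_pairs(exact, max_dist_px = 30)), 1)
})

test_that("pair formation equals the brute-force oracle on random instances", {
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(3:50, 1)
    pk <- unique(data.frame(row = sample(0:60, n, replace = TRUE),
                            col = sample(0:60, n, replace = TRUE)))
    pk$height <- runif(nrow(pk), 0.1, 1)
    got <- form_pairs(pk, 3, 30)
    exp <- form_pairs_oracle(pk, 3, 30)
    expect_equal(nrow(got), nrow(exp))
    if (nrow(got)) {
      got_keys <- sort(pair_keys(got[, c("a_row", "a_col", "b_row", "b_col")]))
      exp_keys <- sort(pair_keys(cbind(pk$row[exp$a], pk$col[exp$a],
                                       pk$row[exp$b], pk$col[exp$b])))
      expect_identical(got_keys, exp_keys)
    }
  }
})

test_that("match_position maps coordinates and finds shifted maxima", {
  s <- peaks_grid(32, 32, rbind(c(10, 20)), 1)
  m <- match_position(list(row = 10, col = 20), s)
  expect_equal(c(m$row, m$col, m$height), c(10, 20, 1))
  expect_true(m$matched)
  # half-size grid: coordinates scale by the dimension ratio
  half <- peaks_grid(16, 16, rbind(c(5, 10)), 1)
  mh <- match_position(list(row = 10, col = 20), half, from_dim = c(32, 32))
  expect_equal(c(mh$row, mh$col), c(5, 10))
  # a 2-px shift inside a 3-px window is recovered
  sh <- peaks_grid(32, 32, rbind(c(12, 22)), 1)
  ms <- match_position(list(row = 10, col = 20), sh, window_px = 3)
  expect_equal(c(ms$row, ms$col), c(12, 22))
  # no local maximum in the box: falls back to the box max, flagged
  ramp <- jres_spectrum(matrix(rep(1:32, each = 32), 32, 32),
                        jres_axis(32, -16, 16, "Hz"),
                        jres_axis(32, 0, 1, "ppm"))   # grid[r, c] = c
  mf <- match_position(list(row = 16, col = 5), ramp, window_px = 2)
  expect_false(mf$matched)
  expect_equal(mf$col, 7)   # highest edge of the box, no local maximum
})

test_that("valley height is the profile minimum between two peaks", {
  # axis-aligned: equals the row-slice minimum
  g <- matrix(0, 8, 32)
  g[4, ] <- c(rep(0, 5), 1, 0.6, 0.3, 0.1, 0.3, 0.6, 1, rep(0, 20))
  s <- jres_spectrum(g, jres_axis(8, -4, 4, "Hz"), jres_axis(32, 0, 1, "ppm"))
  v <- valley_height(s, list(row = 3, col = 5), list(row = 3, col = 11))
  expect_equal(v, 0.1)
  # adjacent pixels: min of the two heights
  a <- list(row = 3, col = 5); b <- list(row = 3, col = 6)
  expect_equal(valley_height(s, a, b), min(s$grid[4, 6:7]))
  # well-separated rendered peaks over a zero baseline
  m <- jres_metabolite("d", list(jres_multiplet(5, 20, lw_f1 = 1.5,
                                                lw_f2 = 0.05)))
  r <- render_metabolite(m, demo_grid())
  pk <- pick_peaks(r, 0.05)
  v2 <- valley_height(r, as.list(pk[1, ]), as.list(pk[2, ]))
  expect_lt(v2, 0.02 * max(r$grid))
  expect_error(valley_height(s, a, a), "distinct")
})

test_that("resolvability has the documented endpoints and properties", {
  expect_equal(resolvability(1, 1, 0), 1)
  expect_equal(resolvability(2, 2, 2), 0)
  expect_equal(resolvability(2, 4, 1.5), 0.5)
  # symmetric in the two peak heights, monotone in the valley
  set.seed(52)
  for (rep in 1:20) {
    hi <- runif(1, 0.5, 2); hj <- runif(1, 0.5, 2)
    v1 <- runif(1, 0, 1); v2 <- v1 + runif(1, 0, 1)
    expect_equal(resolvability(hi, hj, v1), resolvability(hj, hi, v1))
    expect_gte(resolvability(hi, hj, v1), resolvability(hi, hj, v2))
  }
  expect_error(resolvability(0, 1, 0.5), "positive")
  # the min-height variant is available behind the switch
  expect_equal(resolvability(1, 3, 0.5, method = "min"), 0.5)
})

test_that("category bins are closed on the left with 1 included in 'well'", {
  expect_equal(resolvability_category(c(0, 0.19, 0.2, 0.59, 0.6, 1)),
               c("poorly resolved", "poorly resolved", "partially resolved",
                 "partially resolved", "well resolved", "well resolved"))
})

test_that("score_pairs anchors on HR and degrades scores in LR", {
  # doublet resolved in HR, merged after degradation
  m <- jres_metabolite("d", list(jres_multiplet(5, 7, lw_f1 = 2.5,
                                                lw_f2 = 0.08)))
  hr <- render_metabolite(m, demo_grid())
  lr <- degrade(hr)
  pk <- pick_peaks(hr, 0.05)
  prs <- form_pairs(pk, 3, 30)
  expect_equal(nrow(prs), 1)
  rec <- score_pairs(hr, lr, hr, prs)     # SR stand-in: HR itself
  expect_equal(rec$score_sr, rec$score_hr)
  expect_equal(rec$h_i_sr, rec$h_i_hr)
  expect_gt(rec$score_hr, rec$score_lr)
  expect_true(rec$matched_hr)
})

test_that("summaries match a manual spreadsheet computation", {
  rec <- data.frame(
    pair = 1:5, a_row = 0, a_col = 0, b_row = 0, b_col = 0,
    distance_px = c(5, 12, 15, 22, 28),
    score_hr = c(0.9, 0.8, 0.7, 0.95, 0.6),
    score_lr = c(0.2, 0.5, 0.4, 0.7, 0.6),
    score_sr = c(0.8, 0.5, 0.6, 0.9, 0.5))
  s <- summarize_scores(rec)
  expect_equal(s$frac_sr_ge_lr, 4 / 5)    # all but the last two... by hand:
  # pairs: .8>=.2, .5>=.5, .6>=.4, .9>=.7, .5>=.6 -> 4 of 5
  expect_equal(s$frac_sr_gt_lr, 3 / 5)    # strict: excludes the tie
  expect_equal(s$cor_hr_sr, cor(rec$score_hr, rec$score_sr))
  b <- s$bins[s$bins$resolution == "hr" & s$bins$bin_lo == 10, ]
  expect_equal(b$n, 2L)                   # distances 12 and 15
  expect_equal(b$mean, mean(c(0.8, 0.7)))
  # identical SR and HR scores: perfect correlation
  rec2 <- rec; rec2$score_sr <- rec2$score_hr
  expect_equal(summarize_scores(rec2)$cor_hr_sr, 1.0)
  # improvement fraction 1 when every SR score is at least the LR score
  expect_equal(summarize_scores(rec2)$frac_sr_ge_lr, 1.0)
  # degenerate variance: correlation undefined, not NaN
  rec3 <- rec; rec3$score_sr <- 0.5
  s3 <- summarize_scores(rec3)
  expect_false(s3$cor_defined)
  expect_true(is.na(s3$cor_hr_sr))
  expect_error(summarize_scores(rec[1, ]), "at least 2")
})

test_that("reliability counts truth-matched peaks per threshold", {
  set.seed(53)
  at <- cbind(sample(seq(4, 60, by = 6)), sample(seq(4, 60, by = 6)))[1:10, ]
  truth <- peaks_grid(64, 64, at, heights = 1)
  # SR spectrum identical to truth: everything matches at every threshold
  tab <- reliability(truth, truth, truth, thresholds = c(0.01, 0.05, 0.1))
  expect_equal(tab$matched_sr, tab$n_sr)
  # SR detecting 8 true peaks + 2 spurious; LR empty
  sr <- peaks_grid(64, 64, rbind(at[1:8, ], c(1, 62), c(62, 1)),
                   heights = c(rep(1, 8), 0.5, 0.5))
  lr <- peaks_grid(32, 32, matrix(numeric(0), 0, 2))
  tab2 <- reliability(lr, sr, truth, thresholds = 0.1, tol_px = 2)
  expect_equal(tab2$n_sr, 10)
  expect_equal(tab2$matched_sr, 8)
  expect_equal(tab2$n_lr, 0)
  # with no LR peaks the gained fraction spans all SR peaks
  expect_equal(tab2$frac_gained_matched, 0.8)
})
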