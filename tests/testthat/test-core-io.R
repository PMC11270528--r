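test_that("spectrum constructor enforces grid/axis invariants", {
  f1 <- jres_axis(4, -40, 40, "Hz")
  f2 <- jres_axis(8, -3.56, 13.129, "ppm")
  expect_error(jres_spectrum(matrix(0, 4, 7), f1, f2), "axes demand")
  bad <- matrix(0, 4, 8); bad[2, 3] <- NaN
  expect_error(jres_spectrum(bad, f1, f2), "finite")
  expect_error(jres_spectrum(matrix(0, 4, 8), f2, f1), "Hz")
  s <- jres_spectrum(matrix(1, 4, 8), f1, f2)
  expect_identical(dim(s), c(4L, 8L))
})

test_that("flip_f1 reverses rows and is an involution", {
  s <- toy_spectrum(6, 10)
  g <- matrix(0, 6, 10); g[2, 4] <- 1   # pixel at 0-based row 1
  sp <- jres_spectrum(g, jres_axis(6, -3, 3, "Hz"),
                      jres_axis(10, 0, 10, "ppm"))
  expect_equal(flip_f1(sp)$grid[6 - 1, 4], 1)  # row n-1-r = 4 (0-based), R idx 5
  expect_identical(flip_f1(flip_f1(s))$grid, s$grid)
  # an ideally symmetric spectrum is unchanged
  m <- jres_metabolite("x", list(jres_multiplet(5, 7, lw_f1 = 1.5,
                                                lw_f2 = 0.05)))
  r <- render_metabolite(m, demo_grid())
  expect_equal(flip_f1(r)$grid, r$grid, tolerance = 1e-6)
})

test_that("native container round-trips bit-exactly", {
  tmp <- withr::local_tempfile(fileext = ".jres")
  s <- toy_spectrum(4, 8)
  write_spectrum(s, tmp)
  r <- read_spectrum(tmp)
  expect_identical(r$grid, s$grid)
  expect_equal(r$f1_axis, s$f1_axis)
  expect_equal(r$f2_axis, s$f2_axis)
  expect_identical(r$label, s$label)
  # constant-zero round trip
  z <- jres_spectrum(matrix(0, 2, 2), jres_axis(2, -1, 1, "Hz"),
                     jres_axis(2, 0, 1, "ppm"))
  write_spectrum(z, tmp)
  expect_identical(read_spectrum(tmp)$grid, z$grid)
})

test_that("corrupt native containers give explicit parse errors", {
  tmp <- withr::local_tempfile(fileext = ".jres")
  writeLines(c("JRES1", "{\"n_f1\": 4}"), tmp)
  expect_error(read_spectrum(tmp, "jres"), "missing axis metadata")
  s <- toy_spectrum(4, 8)
  write_spectrum(s, tmp)
  # truncate the payload: declared sizes no longer match the data
  full <- readBin(tmp, "raw", file.size(tmp))
  writeBin(full[seq_len(length(full) - 40)], tmp)
  expect_error(read_spectrum(tmp), "truncated")
  expect_error(read_spectrum(file.path(tempdir(), "nope.jres")), "no such file")
})

test_that("NMRPipe 2D files read back grid and axes", {
  # synthetic file built from the documented header word offsets
  tmp <- withr::local_tempfile(fileext = ".ft2")
  hdr <- numeric(512)
  hdr[2 + 1] <- 2.345   # FDFLTORDER
  hdr[99 + 1] <- 8      # FDSIZE (F2 points)
  hdr[219 + 1] <- 4     # FDSPECNUM (F1 points)
  hdr[100 + 1] <- 1200  # FDF2SW (Hz)
  hdr[101 + 1] <- 600   # FDF2ORIG (Hz of last point)
  hdr[119 + 1] <- 600   # FDF2OBS (MHz)
  hdr[229 + 1] <- 80    # FDF1SW (Hz)
  hdr[249 + 1] <- -40   # FDF1ORIG
  set.seed(42)
  g <- matrix(rnorm(32), 4, 8)
  con <- file(tmp, "wb")
  writeBin(hdr, con, size = 4, endian = "little")
  writeBin(as.numeric(t(g)), con, size = 4, endian = "little")  # F2 fastest
  close(con)
  s <- read_spectrum(tmp)
  expect_equal(s$grid, float32_quantize(g))
  expect_equal(s$f2_axis$start, 3)     # (orig + sw) / obs
  expect_equal(s$f2_axis$end, 1)       # orig / obs
  expect_equal(s$f1_axis$start, 40)
  expect_equal(s$f1_axis$end, -40)
  expect_error(read_nmrpipe(withr::local_tempfile(fileext = ".x",
                                                  lines = "not a pipe file")),
               "NMRPipe")
})

test_that("Bruker processed directories read back with NC_proc scaling", {
  dir <- withr::local_tempdir()
  writeLines(c("##$SI= 8", "##$XDIM= 4", "##$SW_p= 1200", "##$SF= 600",
               "##$OFFSET= 3", "##$NC_proc= -2", "##$BYTORDP= 0",
               "##$DTYPP= 0", "##END="), file.path(dir, "procs"))
  writeLines(c("##$SI= 4", "##$XDIM= 2", "##$SW_p= 80", "##END="),
             file.path(dir, "proc2s"))
  set.seed(7)
  ints <- matrix(sample(-1000:1000, 32), 4, 8)
  # serialize in submatrix order: 2x4 blocks, F2 fastest within a block
  vals <- integer()
  for (b1 in 1:2) for (b2 in 1:2) {
    blk <- ints[(b1 - 1) * 2 + 1:2, (b2 - 1) * 4 + 1:4]
    vals <- c(vals, as.integer(t(blk)))
  }
  writeBin(vals, file.path(dir, "2rr"), size = 4, endian = "little")
  s <- read_spectrum(dir)
  expect_equal(s$grid, float32_quantize(ints * 2^-2))
  expect_equal(s$f2_axis$start, 3)
  expect_equal(s$f2_axis$end, 1)           # OFFSET - SW_p / SF
  expect_equal(s$f1_axis$start, -40)
  expect_equal(s$observe_frequency, 600)
})
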