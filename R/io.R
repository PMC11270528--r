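#' Write a spectrum to the native `.jres` container
#'
#' The native container is a single file holding a one-line magic string
#' (`JRES1`), a one-line JSON header (grid dimensions, both axes, observe
#' frequency, label, dtype and byte order), then the grid as little-endian
#' float32 in column-major order (F1 fastest). Because [jres_spectrum()]
#' quantizes intensities to float32 on construction, a write/read round trip
#' reproduces the grid bit-exactly and the axes exactly.
#'
#' @param spectrum a [jres_spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "jres_spectrum"))
  hdr <- list(
    n_f1 = spectrum$f1_axis$n_points, f1_start = spectrum$f1_axis$start,
    f1_end = spectrum$f1_axis$end, f1_unit = spectrum$f1_axis$unit,
    n_f2 = spectrum$f2_axis$n_points, f2_start = spectrum$f2_axis$start,
    f2_end = spectrum$f2_axis$end, f2_unit = spectrum$f2_axis$unit,
    observe_frequency = spectrum$observe_frequency, label = spectrum$label,
    dtype = "float32", byte_order = "little"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("JRES1", jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)),
             con)
  writeBin(as.numeric(spectrum$grid), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a 2D spectrum
#'
#' Reads the native `.jres` container (read/write), an NMRPipe 2D file or a
#' Bruker processed-data directory (both read-only). `format = "auto"`
#' dispatches on the file: directories are taken as Bruker `pdata` level
#' directories, files beginning with the `JRES1` magic as native, anything
#' else is tried as NMRPipe.
#'
#' @param path file (native, NMRPipe) or directory (Bruker) path.
#' @param format one of `"auto"`, `"jres"`, `"nmrpipe"`, `"bruker"`.
#' @return a [jres_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "jres", "nmrpipe", "bruker")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    if (dir.exists(path)) {
      format <- "bruker"
    } else {
      magic <- readBin(path, "raw", n = 5L)
      format <- if (identical(rawToChar(magic), "JRES1")) "jres" else "nmrpipe"
    }
  }
  switch(format,
         jres = read_jres_native(path),
         nmrpipe = read_nmrpipe(path),
         bruker = read_bruker(path))
}

read_jres_native <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "JRES1"))
    stop("not a native .jres file (bad magic): ", path, call. = FALSE)
  hdr <- tryCatch(jsonlite::fromJSON(readLines(con, n = 1L)),
                  error = function(e) stop("unparseable .jres header in ",
                                           path, call. = FALSE))
  need <- c("n_f1", "f1_start", "f1_end", "n_f2", "f2_start", "f2_end")
  if (!all(need %in% names(hdr)))
    stop(".jres header missing axis metadata in ", path, call. = FALSE)
  n <- hdr$n_f1 * hdr$n_f2
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(vals) != n)
    stop(sprintf(".jres payload truncated: expected %d values, got %d",
                 n, length(vals)), call. = FALSE)
  jres_spectrum(matrix(vals, hdr$n_f1, hdr$n_f2),
                jres_axis(hdr$n_f1, hdr$f1_start, hdr$f1_end, "Hz"),
                jres_axis(hdr$n_f2, hdr$f2_start, hdr$f2_end, "ppm"),
                observe_frequency = hdr$observe_frequency %||% 600,
                label = hdr$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NMRPipe header word offsets (0-based, standard fdatap layout)
.pipe <- list(FDMAGIC = 0L, FDFLTORDER = 2L, FDDIMCOUNT = 9L, FDSIZE = 99L,
              FDF2SW = 100L, FDF2ORIG = 101L, FDF2OBS = 119L, FDF1OBS = 218L,
              FDSPECNUM = 219L, FDTRANSPOSED = 221L, FDF1SW = 229L,
              FDF1ORIG = 249L)

#' Read a processed 2D NMRPipe file
#'
#' Minimal reader for real, frequency-domain, untransposed 2D NMRPipe data:
#' 512 float32 header words followed by `FDSIZE x FDSPECNUM` float32
#' intensities stored trace by trace (F2 fastest). Byte order is detected
#' from the FDFLTORDER word (2.345). The F2 axis is reconstructed in ppm from
#' the sweep width, origin and observe frequency; the F1 axis in Hz from its
#' sweep width and origin. NMRPipe origins give the coordinate of the last
#' point, so axes run from `orig + sw` down to `orig` (descending).
#'
#' @param path NMRPipe `.ft2`-style file.
#' @return a [jres_spectrum()].
#' @export
read_nmrpipe <- function(path) {
  hdr <- readBin(path, "numeric", n = 512L, size = 4L, endian = "little")
  if (length(hdr) < 512L) stop("file too short for an NMRPipe header: ", path,
                               call. = FALSE)
  w <- function(off) hdr[off + 1L]
  endian <- "little"
  if (abs(w(.pipe$FDFLTORDER) - 2.345) > 1e-4) {
    hdr <- readBin(path, "numeric", n = 512L, size = 4L, endian = "big")
    endian <- "big"
    if (abs(w(.pipe$FDFLTORDER) - 2.345) > 1e-4)
      stop("not an NMRPipe file (FDFLTORDER != 2.345): ", path, call. = FALSE)
  }
  if (isTRUE(w(.pipe$FDTRANSPOSED) != 0))
    stop("transposed NMRPipe data not supported", call. = FALSE)
  n_f2 <- as.integer(w(.pipe$FDSIZE))
  n_f1 <- as.integer(w(.pipe$FDSPECNUM))
  if (n_f2 < 2L || n_f1 < 2L)
    stop("NMRPipe header has implausible dimensions", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 512L * 4L))
  vals <- readBin(con, "numeric", n = n_f1 * n_f2, size = 4L, endian = endian)
  if (length(vals) != n_f1 * n_f2)
    stop("NMRPipe payload truncated in ", path, call. = FALSE)
  # traces are F2-fastest: fill by row
  grid <- matrix(vals, n_f1, n_f2, byrow = TRUE)
  obs2 <- w(.pipe$FDF2OBS)
  sw2 <- w(.pipe$FDF2SW); orig2 <- w(.pipe$FDF2ORIG)
  sw1 <- w(.pipe$FDF1SW); orig1 <- w(.pipe$FDF1ORIG)
  if (obs2 <= 0 || sw2 <= 0 || sw1 <= 0)
    stop("NMRPipe header missing axis calibration", call. = FALSE)
  f2 <- jres_axis(n_f2, (orig2 + sw2) / obs2, orig2 / obs2, "ppm")
  f1 <- jres_axis(n_f1, orig1 + sw1, orig1, "Hz")
  jres_spectrum(grid, f1, f2, observe_frequency = obs2,
                label = basename(path))
}

#' Read a Bruker processed 2D data directory
#'
#' Minimal reader for a Bruker `pdata/<n>` level directory containing `2rr`,
#' `procs` and `proc2s`. Supports 32-bit integer data (`DTYPP = 0`) in either
#' byte order (`BYTORDP`), applies the `NC_proc` scaling (`value * 2^NC_proc`)
#' and undoes the XDIM submatrix storage layout. The F2 axis is built from
#' `OFFSET` (ppm of the first column) and `SW_p / SF`; the F1 axis of a J-Res
#' experiment is in Hz and is centred on 0 with span `SW_p` from `proc2s`.
#'
#' @param path directory containing `2rr`, `procs`, `proc2s`.
#' @return a [jres_spectrum()].
#' @export
read_bruker <- function(path) {
  need <- file.path(path, c("2rr", "procs", "proc2s"))
  if (!all(file.exists(need)))
    stop("Bruker directory must contain 2rr, procs and proc2s: ", path,
         call. = FALSE)
  p2 <- read_bruker_params(need[2])
  p1 <- read_bruker_params(need[3])
  si2 <- as.integer(p2$SI); si1 <- as.integer(p1$SI)
  xd2 <- as.integer(p2$XDIM %||% si2); xd1 <- as.integer(p1$XDIM %||% 1L)
  if (is.na(si2) || is.na(si1))
    stop("procs/proc2s missing SI", call. = FALSE)
  if ((p2$DTYPP %||% 0) != 0)
    stop("only DTYPP = 0 (int32) Bruker data supported", call. = FALSE)
  endian <- if ((p2$BYTORDP %||% 0) == 0) "little" else "big"
  raw_int <- readBin(need[1], "integer", n = si1 * si2, size = 4L,
                     endian = endian)
  if (length(raw_int) != si1 * si2)
    stop("2rr truncated: expected ", si1 * si2, " points", call. = FALSE)
  vals <- raw_int * 2^(p2$NC_proc %||% 0)
  grid <- bruker_desubmatrix(vals, si1, si2, xd1, xd2)
  sf <- p2$SF %||% 600
  off2 <- p2$OFFSET %||% 0
  sw2_ppm <- (p2$SW_p %||% stop("procs missing SW_p", call. = FALSE)) / sf
  sw1 <- p1$SW_p %||% stop("proc2s missing SW_p", call. = FALSE)
  f2 <- jres_axis(si2, off2, off2 - sw2_ppm, "ppm")
  f1 <- jres_axis(si1, -sw1 / 2, sw1 / 2, "Hz")
  jres_spectrum(grid, f1, f2, observe_frequency = sf, label = basename(path))
}

read_bruker_params <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hits <- grep("^##\\$", lines, value = TRUE)
  keys <- sub("^##\\$([^=]+)=.*$", "\\1", hits)
  vals <- suppressWarnings(as.numeric(sub("^##\\$[^=]+=\\s*", "", hits)))
  out <- as.list(vals)
  names(out) <- keys
  out[!is.na(vals)]
}

# undo Bruker XDIM submatrix storage: data are stored submatrix by submatrix,
# F2 fastest within each xd1 x xd2 block, blocks raster F2-major
bruker_desubmatrix <- function(vals, si1, si2, xd1, xd2) {
  if (si1 %% xd1 != 0 || si2 %% xd2 != 0)
    stop("XDIM does not divide SI", call. = FALSE)
  grid <- matrix(0, si1, si2)
  nb2 <- si2 %/% xd2
  k <- 0L
  for (b1 in seq_len(si1 %/% xd1)) {
    for (b2 in seq_len(nb2)) {
      block <- matrix(vals[k + seq_len(xd1 * xd2)], xd1, xd2, byrow = TRUE)
      grid[(b1 - 1L) * xd1 + seq_len(xd1), (b2 - 1L) * xd2 + seq_len(xd2)] <-
        block
      k <- k + xd1 * xd2
    }
  }
  grid
}
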