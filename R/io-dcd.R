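# DCD binary trajectory reader/writer (CHARMM/NAMD layout, native endianness,
# orthorhombic unit cells). File coordinates are Angstrom; nm in memory.
# Frame time convention: time_ns = (istart + i * nsavc) * delta / 1000 with
# delta interpreted as ps per step.

#' @keywords internal
#' @noRd
read_record <- function(con) {
  len <- readBin(con, "integer", 1L, size = 4L)
  if (length(len) == 0L) return(NULL)
  payload <- readBin(con, "raw", len)
  tail <- readBin(con, "integer", 1L, size = 4L)
  lk_assert(identical(len, tail), "corrupt DCD record framing")
  payload
}

#' @keywords internal
#' @noRd
write_record <- function(con, payload) {
  writeBin(length(payload), con, size = 4L)
  writeBin(payload, con)
  writeBin(length(payload), con, size = 4L)
}

#' Read a DCD trajectory
#'
#' @param path Path to a `.dcd` file.
#' @return List with `coordinates` `[n_frames, n_atoms, 3]` (nm), `box`
#'   `[n_frames, 3]` (nm, `NA` if the file has no unit-cell records) and
#'   `times` (ns).
#' @export
read_dcd <- function(path) {
  lk_assert(file.exists(path), sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_record(con)
  lk_assert(length(hdr) == 84L && rawToChar(hdr[1:4]) == "CORD",
            "not a DCD file (bad header record)")
  icntrl <- readBin(hdr[5:84], "integer", 20L, size = 4L)
  nframes <- icntrl[1]
  istart <- icntrl[2]
  nsavc <- max(icntrl[3], 1L)
  delta <- readBin(hdr[(4 + 9 * 4 + 1):(4 + 10 * 4)], "numeric", 1L, size = 4L)
  has_cell <- icntrl[11] == 1L
  invisible(read_record(con))                      # title block
  natoms <- readBin(read_record(con), "integer", 1L, size = 4L)
  coords <- array(0, dim = c(max(nframes, 1L), natoms, 3L))
  box <- matrix(NA_real_, nrow = max(nframes, 1L), ncol = 3L)
  f <- 0L
  repeat {
    cell <- if (has_cell) read_record(con) else NULL
    if (has_cell && is.null(cell)) break
    xr <- read_record(con)
    if (is.null(xr)) break
    f <- f + 1L
    if (f > dim(coords)[1]) {                       # header undercounted
      coords2 <- array(0, dim = c(f, natoms, 3L))
      coords2[1:(f - 1L), , ] <- coords
      coords <- coords2
      box <- rbind(box, NA_real_)
    }
    if (has_cell) {
      xtl <- readBin(cell, "numeric", 6L, size = 8L)
      box[f, ] <- xtl[c(1, 3, 6)] / 10
    }
    coords[f, , 1] <- readBin(xr, "numeric", natoms, size = 4L)
    coords[f, , 2] <- readBin(read_record(con), "numeric", natoms, size = 4L)
    coords[f, , 3] <- readBin(read_record(con), "numeric", natoms, size = 4L)
  }
  lk_assert(f >= 1L, "DCD contains no frames")
  coords <- coords[seq_len(f), , , drop = FALSE] / 10
  times <- (istart + (seq_len(f) - 1L) * nsavc) * delta / 1000
  list(coordinates = coords, box = box[seq_len(f), , drop = FALSE], times = times)
}

#' Write a DCD trajectory
#'
#' @param frames A [frame_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- frames$n_frames
  dt_ps <- if (nf > 1L) (frames$times[2] - frames$times[1]) * 1000 else 1
  istart <- as.integer(round(frames$times[1] * 1000 / dt_ps))
  hdr <- raw(84)
  hdr[1:4] <- charToRaw("CORD")
  icntrl <- integer(20)
  icntrl[1] <- nf
  icntrl[2] <- istart
  icntrl[3] <- 1L
  icntrl[11] <- 1L
  icntrl[20] <- 24L
  ic_raw <- writeBin(icntrl, raw(), size = 4L)
  ic_raw[(9 * 4 + 1):(10 * 4)] <- writeBin(dt_ps, raw(), size = 4L)
  hdr[5:84] <- ic_raw
  write_record(con, hdr)
  title <- sprintf("%-80s", "lipidkin trajectory")
  write_record(con, c(writeBin(1L, raw(), size = 4L), charToRaw(title)))
  write_record(con, writeBin(frames$n_particles, raw(), size = 4L))
  for (f in seq_len(nf)) {
    bx <- frames$box[f, ] * 10
    write_record(con, writeBin(c(bx[1], 0, bx[2], 0, 0, bx[3]), raw(), size = 8L))
    xyz <- matrix(frames$coordinates[f, , ], ncol = 3L) * 10
    for (k in 1:3) write_record(con, writeBin(xyz[, k], raw(), size = 4L))
  }
  invisible(path)
}
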