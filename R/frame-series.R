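#' Trajectory frames container
#'
#' A `FrameSeries` stores per-frame coordinates, simulation times and
#' orthorhombic box dimensions for one trajectory replicate. Units are nm and
#' ns throughout; conversions from file formats happen at the I/O boundary.
#'
#' @param coordinates Numeric array `[n_frames, n_particles, 3]` in nm.
#' @param times Numeric vector of frame times in ns, strictly increasing.
#' @param box Numeric matrix `[n_frames, 3]` of box edge lengths in nm, or a
#'   length-3 vector recycled to all frames.
#'
#' @return A list of class `FrameSeries` with elements `coordinates`, `times`,
#'   `box`, `n_frames`, `n_particles`.
#' @export
frame_series <- function(coordinates, times, box) {
  lk_assert(is.array(coordinates) && length(dim(coordinates)) == 3L &&
              dim(coordinates)[3] == 3L,
            "coordinates must be an [n_frames, n_particles, 3] array")
  nf <- dim(coordinates)[1]
  np <- dim(coordinates)[2]
  lk_assert(nf >= 1L, "FrameSeries needs at least one frame")
  lk_assert(length(times) == nf, "times length must equal n_frames")
  lk_assert(nf < 2L || all(diff(times) > 0), "times must be strictly increasing")
  if (is.null(dim(box))) {
    lk_assert(length(box) == 3L, "box must be [n_frames, 3] or length 3")
    box <- matrix(box, nrow = nf, ncol = 3L, byrow = TRUE)
  }
  lk_assert(is.matrix(box) && nrow(box) == nf && ncol(box) == 3L,
            "box must be an [n_frames, 3] matrix")
  lk_assert(all(box > 0), "all box lengths must be > 0")
  structure(
    list(coordinates = coordinates, times = as.numeric(times), box = box,
         n_frames = nf, n_particles = np),
    class = "FrameSeries"
  )
}

#' @export
print.FrameSeries <- function(x, ...) {
  cat(sprintf(
    "FrameSeries: %d frame(s), %d particles, t = [%.4g, %.4g] ns, box[1] = %s nm\n",
    x$n_frames, x$n_particles, x$times[1], x$times[x$n_frames],
    paste(sprintf("%.3f", x$box[1, ]), collapse = " x ")))
  invisible(x)
}

#' Extract one frame's coordinates
#' @param frames A [frame_series()].
#' @param i Frame number, 0-based (frames are 0-based package-wide).
#' @return `[n_particles, 3]` coordinate matrix (nm).
#' @export
frame_coords <- function(frames, i = 0L) {
  lk_assert(i >= 0L && i < frames$n_frames, "frame index out of range")
  matrix(frames$coordinates[i + 1L, , ], ncol = 3L)
}

#' Check that a FrameSeries matches a ParticleMeta
#' @keywords internal
#' @noRd
check_system <- function(meta, frames) {
  lk_assert(frames$n_particles == n_particles(meta),
            sprintf("FrameSeries has %d particles but ParticleMeta has %d",
                    frames$n_particles, n_particles(meta)))
  invisible(TRUE)
}
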