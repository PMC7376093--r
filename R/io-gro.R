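# GRO reader/writer. Coordinates are nm in the file and in memory.
# Multi-frame GRO files (concatenated blocks, "t=" in the title) are read as
# trajectories.

#' Read a GRO file
#'
#' @param path Path to a `.gro` file; may contain several concatenated frames.
#' @return List with `atoms` (data.frame: residue_id, residue_name,
#'   particle_name), `coordinates` array `[n_frames, n_atoms, 3]` (nm),
#'   `box` matrix (nm) and `times` (ns; 0-based frame index when the title
#'   carries no `t=`).
#' @export
read_gro <- function(path) {
  lk_assert(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path)
  frames <- list()
  boxes <- list()
  times <- numeric(0)
  i <- 1L
  atoms <- NULL
  while (i <= length(lines) && nzchar(trimws(paste(lines[i], collapse = "")))) {
    title <- lines[i]
    nat <- as.integer(trimws(lines[i + 1L]))
    lk_assert(is.finite(nat) && nat > 0, "bad GRO atom count")
    block <- lines[(i + 2L):(i + 1L + nat)]
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])
    lk_assert(length(boxline) >= 3L && all(is.finite(boxline[1:3])),
              "bad GRO box line")
    if (length(boxline) > 3L && any(abs(boxline[4:length(boxline)]) > 1e-9)) {
      lk_error("triclinic boxes are not supported (orthorhombic only)",
               "lipidkin_triclinic_box")
    }
    if (is.null(atoms)) {
      atoms <- data.frame(
        residue_id = as.integer(substr(block, 1, 5)),
        residue_name = trimws(substr(block, 6, 10)),
        particle_name = trimws(substr(block, 11, 15)),
        stringsAsFactors = FALSE
      )
    }
    xyz <- cbind(as.numeric(substr(block, 21, 28)),
                 as.numeric(substr(block, 29, 36)),
                 as.numeric(substr(block, 37, 44)))
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- boxline[1:3]
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2]) / 1000 else NA_real_)
    i <- i + 3L + nat
    if (i <= length(lines) && !nzchar(trimws(lines[i] %||% ""))) break
  }
  nf <- length(frames)
  if (anyNA(times)) times <- seq_len(nf) - 1
  coords <- array(0, dim = c(nf, nrow(atoms), 3L))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  list(atoms = atoms, coordinates = coords,
       box = do.call(rbind, boxes), times = times)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Write a system to a GRO file
#'
#' @param meta A [particle_meta()].
#' @param frames A [frame_series()]; all frames are written (times stored as
#'   `t=` in ps in each frame title).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(meta, frames, path) {
  check_system(meta, frames)
  con <- file(path, "w")
  on.exit(close(con))
  np <- n_particles(meta)
  resid5 <- meta$residue_id %% 100000L
  for (f in seq_len(frames$n_frames)) {
    xyz <- matrix(frames$coordinates[f, , ], ncol = 3L)
    writeLines(sprintf("lipidkin system, t= %.4f", frames$times[f] * 1000), con)
    writeLines(sprintf("%5d", np), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid5, substr(meta$residue_name, 1, 5),
                       substr(meta$particle_name, 1, 5),
                       (seq_len(np)) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       frames$box[f, 1], frames$box[f, 2], frames$box[f, 3]), con)
  }
  invisible(path)
}
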