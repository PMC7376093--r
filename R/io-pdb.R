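# PDB reader/writer. File coordinates are Angstrom; converted to nm on read.
# MODEL/ENDMDL blocks are read as trajectory frames.

#' Read a PDB file
#'
#' @param path Path to a `.pdb` file; multiple `MODEL` blocks become frames.
#' @return List with `atoms` (residue_id, residue_name, segment_id,
#'   particle_name, bfactor), `coordinates` `[n_frames, n_atoms, 3]` in nm,
#'   `box` (nm; `NA` row if no CRYST1 record) and `times` (frame indices).
#' @export
read_pdb <- function(path) {
  lk_assert(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path)
  box <- c(NA_real_, NA_real_, NA_real_)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst) >= 1L) {
    a <- as.numeric(substr(cryst[1], 7, 15))
    b <- as.numeric(substr(cryst[1], 16, 24))
    c3 <- as.numeric(substr(cryst[1], 25, 33))
    ang <- c(as.numeric(substr(cryst[1], 34, 40)),
             as.numeric(substr(cryst[1], 41, 47)),
             as.numeric(substr(cryst[1], 48, 54)))
    if (any(abs(ang - 90) > 1e-3)) {
      lk_error("triclinic boxes are not supported (orthorhombic only)",
               "lipidkin_triclinic_box")
    }
    box <- c(a, b, c3) / 10
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) <= 1L) {
    blocks <- list(lines[is_atom])
  } else {
    bounds <- c(model_starts, length(lines) + 1L)
    blocks <- lapply(seq_along(model_starts), function(k) {
      seg <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
      seg[grepl("^(ATOM  |HETATM)", seg)]
    })
  }
  first <- blocks[[1]]
  lk_assert(length(first) > 0L, "no ATOM/HETATM records in PDB")
  atoms <- data.frame(
    residue_id = as.integer(substr(first, 23, 26)),
    residue_name = trimws(substr(first, 18, 21)),
    segment_id = trimws(substr(first, 22, 22)),
    particle_name = trimws(substr(first, 13, 16)),
    bfactor = suppressWarnings(as.numeric(substr(first, 61, 66))),
    stringsAsFactors = FALSE
  )
  atoms$segment_id[!nzchar(atoms$segment_id)] <- "A"
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  nf <- length(blocks)
  coords <- array(0, dim = c(nf, nrow(atoms), 3L))
  for (f in seq_len(nf)) {
    bl <- blocks[[f]]
    lk_assert(length(bl) == nrow(atoms), "PDB MODEL blocks differ in atom count")
    coords[f, , ] <- cbind(as.numeric(substr(bl, 31, 38)),
                           as.numeric(substr(bl, 39, 46)),
                           as.numeric(substr(bl, 47, 54))) / 10
  }
  list(atoms = atoms, coordinates = coords, box = box, times = seq_len(nf) - 1)
}

#' Write a system to a PDB file
#'
#' @param meta A [particle_meta()].
#' @param frames A [frame_series()]; several frames become `MODEL` blocks.
#' @param path Output path.
#' @param bfactor Numeric vector of per-particle B-factors (default 0).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(meta, frames, path, bfactor = NULL) {
  check_system(meta, frames)
  np <- n_particles(meta)
  if (is.null(bfactor)) bfactor <- rep(0, np)
  lk_assert(length(bfactor) == np, "bfactor length must equal particle count")
  lk_assert(all(is.finite(bfactor)), "non-finite B-factor values")
  con <- file(path, "w")
  on.exit(close(con))
  bx <- frames$box[1, ] * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     bx[1], bx[2], bx[3], 90, 90, 90), con)
  multi <- frames$n_frames > 1L
  name4 <- sprintf("%-4s", substr(meta$particle_name, 1, 4))
  short <- nchar(trimws(name4)) <= 3L
  name4[short] <- sprintf(" %-3s", trimws(name4[short]))
  for (f in seq_len(frames$n_frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- matrix(frames$coordinates[f, , ], ncol = 3L) * 10
    # columns: serial 7-11, name 13-16, resName 18-21, chain 22, resSeq 23-26
    writeLines(sprintf(
      "ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(np) %% 100000L, name4,
      substr(meta$residue_name, 1, 4), substr(meta$segment_id, 1, 1),
      meta$residue_id %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3],
      1.00, bfactor), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Map per-residue scalars onto the B-factor column of a PDB
#'
#' Writes one frame with each atom's B-factor set to its residue's value after
#' a linear rescale to `[0, 99.99]` (the printable B-factor range). Residues
#' absent from `values` get 0.00. Used to paint per-residue residence times or
#' occupancies onto a structure for molecular viewers.
#'
#' @param meta A [particle_meta()].
#' @param frames A [frame_series()]; frame `frame` is written.
#' @param values Named numeric vector, names are residue_ids.
#' @param path Output PDB path.
#' @param frame 0-based frame to write (default 0).
#' @return `path`, invisibly.
#' @export
write_residue_scalar_pdb <- function(meta, frames, values, path, frame = 0L) {
  check_system(meta, frames)
  lk_assert(is.numeric(values) && !is.null(names(values)),
            "values must be a named numeric vector (names = residue_id)")
  if (any(!is.finite(values))) {
    lk_error("non-finite values in residue scalar map", "lipidkin_nonfinite")
  }
  rid <- as.integer(names(values))
  lk_assert(all(rid %in% meta$residue_id),
            "values keyed by residue_id absent from the system")
  rng <- range(values)
  scaled <- if (diff(rng) > 0) (values - rng[1]) / diff(rng) * 99.99 else
    rep(0, length(values))
  b <- rep(0, n_particles(meta))
  match_idx <- match(meta$residue_id, rid)
  b[!is.na(match_idx)] <- scaled[match_idx[!is.na(match_idx)]]
  one <- frame_series(
    array(frames$coordinates[frame + 1L, , ],
          dim = c(1L, frames$n_particles, 3L)),
    frames$times[frame + 1L], frames$box[frame + 1L, , drop = FALSE])
  write_pdb(meta, one, path, bfactor = b)
}
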