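#' Load a topology (and optionally a trajectory) into the package data model
#'
#' Reads a PDB or GRO topology, classifies particles as protein / lipid /
#' other, and attaches trajectory frames from a DCD, multi-frame GRO, or
#' multi-MODEL PDB. With no trajectory, the topology coordinates become a
#' single frame. Coordinates are stored in nm, times in ns, regardless of the
#' source format's units.
#'
#' Lipid classification is driven entirely by `species_map`: force-field
#' naming (MARTINI beads vs atomistic atoms) is user configuration, never
#' hard-coded. Residue names that are neither standard amino acids nor in the
#' map become `category = "other"` with a warning.
#'
#' @param topology_path PDB or GRO file.
#' @param trajectory_path Optional DCD/GRO/PDB trajectory whose particle count
#'   must match the topology. XTC/TRR are not supported (no offline reader)
#'   and raise a structured error.
#' @param species_map Named list: `residue_name -> list(species =, headgroups
#'   = c(...))`. May be empty if the system has no lipids.
#' @param box Optional length-3 numeric (nm) overriding/filling the box when
#'   the topology lacks one.
#' @return List with elements `meta` ([particle_meta()]) and `frames`
#'   ([frame_series()]).
#' @export
load_system <- function(topology_path, trajectory_path = NULL,
                        species_map = list(), box = NULL) {
  ext <- tolower(tools::file_ext(topology_path))
  top <- switch(ext,
    gro = read_gro(topology_path),
    pdb = read_pdb(topology_path),
    lk_error(sprintf("unsupported topology format '.%s' (need PDB or GRO)", ext),
             "lipidkin_unsupported_format")
  )
  atoms <- top$atoms
  if (is.null(atoms$segment_id)) atoms$segment_id <- "A"
  category <- ifelse(atoms$residue_name %in% AA_RESNAMES, "protein",
                     ifelse(atoms$residue_name %in% names(species_map),
                            "lipid", "other"))
  species <- rep("", nrow(atoms))
  for (rn in intersect(names(species_map), atoms$residue_name)) {
    species[atoms$residue_name == rn] <- species_map[[rn]]$species
  }
  unknown <- unique(atoms$residue_name[category == "other"])
  if (length(unknown) > 0L) {
    warning(sprintf("residue name(s) not protein and absent from species_map, set category=other: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  meta <- particle_meta(seq_len(nrow(atoms)) - 1L, atoms$residue_id,
                        atoms$residue_name, atoms$segment_id,
                        atoms$particle_name, category, species)

  if (is.null(trajectory_path)) {
    coords <- top$coordinates
    times <- top$times
    bx <- top$box
  } else {
    text <- tolower(tools::file_ext(trajectory_path))
    if (text %in% c("xtc", "trr")) {
      lk_error(sprintf(
        "trajectory format '.%s' is not supported offline; convert to DCD or multi-frame GRO",
        text), "lipidkin_unsupported_format")
    }
    trj <- switch(text,
      dcd = read_dcd(trajectory_path),
      gro = read_gro(trajectory_path),
      pdb = read_pdb(trajectory_path),
      lk_error(sprintf("unsupported trajectory format '.%s'", text),
               "lipidkin_unsupported_format")
    )
    if (dim(trj$coordinates)[2] != nrow(atoms)) {
      lk_error(sprintf(
        "particle-count mismatch: topology has %d particles, trajectory has %d",
        nrow(atoms), dim(trj$coordinates)[2]), "lipidkin_particle_mismatch")
    }
    coords <- trj$coordinates
    times <- trj$times
    bx <- trj$box
  }
  if (is.null(dim(bx))) bx <- matrix(bx, nrow = dim(coords)[1], ncol = 3L,
                                     byrow = TRUE)
  if (anyNA(bx)) {
    lk_assert(!is.null(box), "topology/trajectory carries no box; supply `box`")
    bx <- matrix(box, nrow = dim(coords)[1], ncol = 3L, byrow = TRUE)
  }
  frames <- frame_series(coords, times, bx)
  check_system(meta, frames)
  list(meta = meta, frames = frames)
}

#' Write a system as GRO topology + DCD trajectory
#'
#' @param meta A [particle_meta()].
#' @param frames A [frame_series()].
#' @param prefix Output path prefix; writes `<prefix>.gro` (frame 0) and
#'   `<prefix>.dcd` (all frames).
#' @return Character vector of the two paths, invisibly.
#' @export
save_system <- function(meta, frames, prefix) {
  check_system(meta, frames)
  one <- frame_series(
    array(frames$coordinates[1, , ], dim = c(1L, frames$n_particles, 3L)),
    frames$times[1], frames$box[1, , drop = FALSE])
  gro <- paste0(prefix, ".gro")
  dcd <- paste0(prefix, ".dcd")
  write_gro(meta, one, gro)
  write_dcd(frames, dcd)
  invisible(c(gro, dcd))
}
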