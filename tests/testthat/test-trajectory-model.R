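# Data model and file I/O.

make_toy_system <- function(nf = 1L, np = 3L, box = c(5, 5, 5)) {
  meta <- particle_meta(
    particle_index = seq_len(np) - 1L,
    residue_id = seq_len(np),
    residue_name = rep("ALA", np),
    segment_id = rep("A", np),
    particle_name = rep("CA", np),
    category = rep("protein", np),
    species = rep("", np)
  )
  coords <- array(round(runif(nf * np * 3, 0.1, 4.9), 3), dim = c(nf, np, 3L))
  list(meta = meta, frames = frame_series(coords, (seq_len(nf) - 1) * 0.5, box))
}

test_that("GRO round trip preserves coordinates to 3 decimals (nm)", {
  set.seed(11)
  sys <- make_toy_system(nf = 3L, np = 5L)
  path <- tempfile(fileext = ".gro")
  write_gro(sys$meta, sys$frames, path)
  back <- read_gro(path)
  expect_equal(dim(back$coordinates), dim(sys$frames$coordinates))
  expect_equal(back$coordinates, sys$frames$coordinates, tolerance = 1e-12)
  expect_equal(back$times, sys$frames$times)
  expect_equal(back$box, sys$frames$box, ignore_attr = TRUE)
  expect_equal(back$atoms$residue_name, sys$meta$residue_name)
})

test_that("PDB round trip preserves coordinates to 3 decimals (Angstrom)", {
  set.seed(12)
  sys <- make_toy_system(nf = 2L, np = 4L)
  path <- tempfile(fileext = ".pdb")
  write_pdb(sys$meta, sys$frames, path)
  back <- read_pdb(path)
  # 3-decimal Angstrom file precision = 1e-4 nm
  expect_equal(back$coordinates, sys$frames$coordinates, tolerance = 1e-9)
  expect_true(max(abs(back$coordinates - sys$frames$coordinates)) < 1e-4 + 1e-12)
  expect_equal(back$atoms$residue_id, sys$meta$residue_id)
})

test_that("DCD round trip preserves coordinates to float32 precision", {
  set.seed(13)
  sys <- make_toy_system(nf = 4L, np = 7L)
  path <- tempfile(fileext = ".dcd")
  write_dcd(sys$frames, path)
  back <- read_dcd(path)
  expect_equal(dim(back$coordinates), dim(sys$frames$coordinates))
  expect_lt(max(abs(back$coordinates - sys$frames$coordinates)), 1e-5)
  expect_equal(back$box, sys$frames$box, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(back$times, sys$frames$times, tolerance = 1e-5)
})

test_that("load_system reads a GRO identically and classifies particles", {
  gro <- c(
    "toy system",
    "    3",
    "    1ALA    CA    1   1.000   2.000   3.000",
    "    2POPC  PO4    2   2.500   2.500   1.200",
    "    3XYZ    Q1    3   0.100   0.200   0.300",
    "   5.00000   5.00000   5.00000")
  path <- tempfile(fileext = ".gro")
  writeLines(gro, path)
  expect_warning(
    sys <- load_system(path, species_map = list(
      POPC = list(species = "POPC", headgroups = "PO4"))),
    "category=other")
  expect_equal(sys$frames$n_frames, 1L)
  expect_equal(frame_coords(sys$frames)[1, ], c(1, 2, 3))
  expect_equal(sys$meta$category, c("protein", "lipid", "other"))
  expect_equal(sys$meta$species, c("", "POPC", ""))
})

test_that("PDB coordinates are converted from Angstrom to nm", {
  sys <- make_toy_system()
  path <- tempfile(fileext = ".pdb")
  write_pdb(sys$meta, sys$frames, path)
  raw_x <- as.numeric(substr(grep("^ATOM", readLines(path), value = TRUE), 31, 38))
  loaded <- load_system(path)
  expect_equal(loaded$frames$coordinates[1, , 1], raw_x / 10, tolerance = 1e-9)
})

test_that("trajectory frame times pass through and counts must match", {
  sys <- make_toy_system(nf = 100L)
  # dt = 1 ns series
  frames <- frame_series(sys$frames$coordinates, seq_len(100) - 1, c(5, 5, 5))
  top <- tempfile(fileext = ".gro")
  trj <- tempfile(fileext = ".dcd")
  one <- frame_series(array(frames$coordinates[1, , ], dim = c(1, 3, 3)),
                      0, c(5, 5, 5))
  write_gro(sys$meta, one, top)
  write_dcd(frames, trj)
  loaded <- load_system(top, trj)
  expect_equal(loaded$frames$n_frames, 100L)
  expect_equal(loaded$frames$times, 0:99, tolerance = 1e-4)

  # particle-count mismatch names both counts
  sys2 <- make_toy_system(np = 5L)
  trj2 <- tempfile(fileext = ".dcd")
  write_dcd(sys2$frames, trj2)
  err <- tryCatch(load_system(top, trj2), error = function(e) e)
  expect_s3_class(err, "lipidkin_particle_mismatch")
  expect_match(conditionMessage(err), "3")
  expect_match(conditionMessage(err), "5")
})

test_that("XTC/TRR trajectories are declined with a structured error", {
  sys <- make_toy_system()
  top <- tempfile(fileext = ".gro")
  write_gro(sys$meta, sys$frames, top)
  fake <- tempfile(fileext = ".xtc")
  writeLines("", fake)
  expect_error(load_system(top, fake), class = "lipidkin_unsupported_format")
})

test_that("selection resolution: inclusive ranges, idempotence, empty errors", {
  np <- 200L
  meta <- particle_meta(seq_len(np) - 1L, seq_len(np), rep("ALA", np),
                       rep("A", np), rep("CA", np), rep("protein", np),
                       rep("", np))
  idx <- resolve_selection(meta, "residue_id 27-132 and category protein")
  expect_equal(sort(meta$residue_id[idx + 1L]), 27:132)
  # idempotent / order-independent
  expect_identical(idx, resolve_selection(meta, "category protein and residue_id 27-132"))
  expect_identical(idx, resolve_selection(meta, "residue_id 27-132 and category protein"))
  expect_error(resolve_selection(meta, "residue_id 500-600"),
               class = "lipidkin_empty_selection")
})

test_that("selection picks species headgroup particles only", {
  meta <- particle_meta(
    0:5, c(1L, 1L, 2L, 2L, 3L, 3L),
    c("GM3", "GM3", "GM3", "GM3", "POPC", "POPC"),
    rep("L", 6), c("GM1", "C1A", "GM1", "C1A", "PO4", "C1A"),
    rep("lipid", 6), c("GM3", "GM3", "GM3", "GM3", "POPC", "POPC"))
  idx <- resolve_selection(meta, "species GM3 and particle_name in (GM1 GM2)")
  expect_equal(idx, c(0L, 2L))
})

test_that("B-factor mapping rescales to [0, 99.99] and round trips", {
  sys <- make_toy_system(np = 3L)
  path <- tempfile(fileext = ".pdb")
  write_residue_scalar_pdb(sys$meta, sys$frames,
                           c(`1` = 0, `2` = 50, `3` = 100), path)
  back <- read_pdb(path)
  expect_equal(back$atoms$bfactor, c(0, 50, 99.99), tolerance = 3e-4)

  # all-zero map stays zero
  write_residue_scalar_pdb(sys$meta, sys$frames,
                           c(`1` = 0, `2` = 0, `3` = 0), path)
  expect_equal(read_pdb(path)$atoms$bfactor, c(0, 0, 0))

  # missing residues get 0.00; the mapped range spans [0, 99.99]
  write_residue_scalar_pdb(sys$meta, sys$frames, c(`2` = 3, `3` = 9), path)
  b <- read_pdb(path)$atoms$bfactor
  expect_equal(b, c(0, 0, 99.99), tolerance = 1e-6)

  expect_error(
    write_residue_scalar_pdb(sys$meta, sys$frames, c(`1` = NaN), path),
    class = "lipidkin_nonfinite")
})

test_that("triclinic boxes are rejected", {
  lines <- c("CRYST1   50.000   50.000   50.000  90.00  95.00  90.00 P 1",
             "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00",
             "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_error(read_pdb(path), class = "lipidkin_triclinic_box")
})
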