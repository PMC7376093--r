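# Plane angles, superposition, RMSD, PCA.

angle_system <- function(tripletA, tripletB) {
  pts <- rbind(tripletA, tripletB)
  meta <- particle_meta(0:5, c(1:3, 101:103), rep("ALA", 6), rep("A", 6),
                       rep("CA", 6), rep("protein", 6), rep("", 6))
  frames <- frame_series(array(pts, dim = c(1, 6, 3)), 0, c(50, 50, 50))
  list(meta = meta, frames = frames)
}

measure_angle <- function(tripletA, tripletB) {
  sys <- angle_system(tripletA, tripletB)
  interdomain_angle(sys$frames, plane_spec(1:3, 101:103, "CA"), sys$meta)$angle_deg
}

tri_xy <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))   # normal +z

test_that("plane angle closed forms: 0, 90, 135, 180 degrees", {
  expect_equal(measure_angle(tri_xy, tri_xy), 0, tolerance = 1e-9)
  # normal +z vs normal -y (xz-plane, counterclockwise seen from -y)
  tri_xz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_equal(measure_angle(tri_xy, tri_xz), 90, tolerance = 1e-9)
  # rotate the xy triplet 135 degrees about x
  R <- matrix(c(1, 0, 0,
                0, cos(3 * pi / 4), -sin(3 * pi / 4),
                0, sin(3 * pi / 4), cos(3 * pi / 4)), 3, 3, byrow = TRUE)
  expect_equal(measure_angle(tri_xy, tri_xy %*% t(R)), 135, tolerance = 1e-9)
  # swapping two vertices flips the normal
  expect_equal(measure_angle(tri_xy, tri_xy[c(2, 1, 3), ]), 180,
               tolerance = 1e-9)
})

test_that("angle is symmetric and vertex reversal maps t to 180 - t", {
  set.seed(41)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3)
    B <- matrix(rnorm(9), 3)
    t1 <- measure_angle(A, B)
    expect_equal(t1, measure_angle(B, A), tolerance = 1e-9)
    expect_equal(measure_angle(A, B[c(1, 3, 2), ]), 180 - t1, tolerance = 1e-6)
  }
})

test_that("angle is invariant under rigid motion of the whole system", {
  set.seed(42)
  A <- matrix(rnorm(9), 3)
  B <- matrix(rnorm(9), 3)
  t0 <- measure_angle(A, B)
  for (i in 1:100) {
    M <- random_rigid_transform(rbind(A, B))
    expect_equal(measure_angle(M[1:3, ], M[4:6, ]), t0, tolerance = 1e-6)
  }
})

test_that("collinear triplets are excluded per frame with a warning", {
  good <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  pts1 <- rbind(good, good + 3)
  pts2 <- rbind(bad, good + 3)
  coords <- array(0, dim = c(2, 6, 3))
  coords[1, , ] <- pts1
  coords[2, , ] <- pts2
  meta <- angle_system(good, good)$meta
  frames <- frame_series(coords, 0:1, c(50, 50, 50))
  expect_warning(
    ang <- interdomain_angle(frames, plane_spec(1:3, 101:103, "CA"), meta),
    "collinear")
  expect_equal(nrow(ang), 1L)
  expect_equal(attr(ang, "errors"), 1L)
})

test_that("superposition: identity and pure translation recover exactly", {
  set.seed(43)
  X <- matrix(rnorm(30), 10)
  s1 <- superpose(X, X)
  expect_lt(s1$rmsd, 1e-12)
  expect_equal(s1$rotation, diag(3), tolerance = 1e-9)

  Y <- sweep(X, 2, c(1, 2, 3), "+")
  s2 <- superpose(Y, X)
  expect_lt(s2$rmsd, 1e-12)
  expect_equal(s2$translation, c(-1, -2, -3), tolerance = 1e-9)
})

test_that("superposition undoes a random rotation and beats random search", {
  set.seed(44)
  X <- matrix(rnorm(150), 50)
  M <- random_rigid_transform(X)
  expect_lt(superpose(M, X)$rmsd, 1e-9)

  # 5-point toys with noise: Kabsch must match the random-rotation oracle
  for (i in 1:3) {
    A <- matrix(rnorm(15), 5)
    B <- A + matrix(rnorm(15, 0, 0.1), 5)
    kb <- superpose(B, A)$rmsd
    orc <- oracle_superpose_rmsd(B, A, n_rot = 20000L)
    expect_lte(kb, orc + 1e-12)        # never worse than the search
    expect_lt(abs(kb - orc), 0.05 * max(orc, 0.01))
  }
})

test_that("domain RMSD: identical frames and rigid motion give zero", {
  set.seed(45)
  X <- matrix(rnorm(60), 20)
  nf <- 4L
  coords <- array(0, dim = c(nf, 20, 3))
  for (f in seq_len(nf)) coords[f, , ] <- X
  meta <- particle_meta(0:19, 1:20, rep("ALA", 20), rep("A", 20),
                       rep("CA", 20), rep("protein", 20), rep("", 20))
  frames <- frame_series(coords, 0:3, c(50, 50, 50))
  rd <- domain_rmsd(frames, meta, "residue_id 1-10", "residue_id 11-20")
  expect_true(all(rd$rmsd_nm < 1e-12))

  for (f in 2:nf) coords[f, , ] <- random_rigid_transform(X)
  frames2 <- frame_series(coords, 0:3, c(50, 50, 50))
  rd2 <- domain_rmsd(frames2, meta, "residue_id 1-10", "residue_id 11-20")
  expect_true(all(rd2$rmsd_nm < 1e-9))
})

test_that("uniform displacement of the measured domain reads as that d", {
  set.seed(46)
  X <- matrix(rnorm(60), 20)
  coords <- array(0, dim = c(2, 20, 3))
  coords[1, , ] <- X
  X2 <- X
  X2[11:20, 3] <- X2[11:20, 3] + 0.7       # fit selection untouched
  coords[2, , ] <- X2
  meta <- particle_meta(0:19, 1:20, rep("ALA", 20), rep("A", 20),
                       rep("CA", 20), rep("protein", 20), rep("", 20))
  frames <- frame_series(coords, 0:1, c(50, 50, 50))
  rd <- domain_rmsd(frames, meta, "residue_id 1-10", "residue_id 11-20")
  expect_equal(rd$rmsd_nm, c(0, 0.7), tolerance = 1e-9)
})

pca_system <- function(coords) {
  np <- dim(coords)[2]
  meta <- particle_meta(0:(np - 1L), 1:np, rep("ALA", np), rep("A", np),
                       rep("CA", np), rep("protein", np), rep("", np))
  frames <- frame_series(coords, seq_len(dim(coords)[1]) - 1, c(50, 50, 50))
  list(meta = meta, frames = frames)
}

test_that("PCA: a single collective mode carries all variance", {
  # particles 0-4 are a static anchor (fit is then exactly the identity);
  # particles 5-9 move along one collective direction
  set.seed(47)
  base <- matrix(rnorm(30), 10)
  dirn <- matrix(rnorm(15), 5); dirn <- dirn / sqrt(sum(dirn^2))
  nf <- 200L
  amp <- sin(seq(0, 6 * pi, length.out = nf))
  coords <- array(0, dim = c(nf, 10, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- base
    coords[f, 6:10, ] <- base[6:10, ] + amp[f] * dirn
  }
  sys <- pca_system(coords)
  pc <- suppressWarnings(
    trajectory_pca(sys$frames, sys$meta, fit_selection = 0:4,
                   analysis_selection = 5:9))
  expect_equal(pc$fraction_first, 1.0, tolerance = 1e-10)
})

test_that("PCA: eigenvalue sum equals total variance; identical frames error", {
  set.seed(48)
  nf <- 100L
  coords <- array(rnorm(nf * 8 * 3, sd = 0.2), dim = c(nf, 8, 3))
  coords <- sweep(coords, c(2, 3), array(5, dim = c(8, 3)), "+")
  sys <- pca_system(coords)
  # no superposition effects: fit on a rigid, motionless anchor is not
  # possible here, so fit and analysis share the selection
  pc <- suppressWarnings(
    trajectory_pca(sys$frames, sys$meta, 0:7, 0:7))
  expect_equal(sum(pc$eigenvalues), pc$total_variance, tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  expect_true(all(pc$eigenvalues >= -1e-12))
  # orthonormal eigenvectors
  G <- t(pc$eigenvectors) %*% pc$eigenvectors
  expect_equal(G, diag(ncol(G)), tolerance = 1e-9)

  same <- array(1, dim = c(10, 8, 3))
  same <- sweep(same, c(2, 3), array(seq_len(24), dim = c(8, 3)), "+")
  sys2 <- pca_system(same)
  expect_error(suppressWarnings(trajectory_pca(sys2$frames, sys2$meta, 0:7, 0:7)),
               class = "lipidkin_no_motion")
})
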