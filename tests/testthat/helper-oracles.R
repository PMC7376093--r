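# Independent oracles used by unit and acceptance tests. These deliberately
# use the dumbest correct algorithm (explicit loops, full image enumeration,
# random search) so they share no code path with the implementation.

# per-frame dual-cutoff state machine, one distance series
oracle_contacts <- function(d, d_on, d_off) {
  bound <- FALSE
  start <- NA_integer_
  ev <- list()
  for (f in seq_along(d)) {
    if (!bound) {
      if (d[f] < d_on) {
        bound <- TRUE
        start <- f - 1L
      }
    } else {
      if (d[f] > d_off) {
        ev[[length(ev) + 1L]] <- c(start, f - 2L)
        bound <- FALSE
      }
    }
  }
  if (bound) ev[[length(ev) + 1L]] <- c(start, length(d) - 1L)
  if (length(ev) == 0L) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  }
  m <- do.call(rbind, ev)
  data.frame(start_frame = m[, 1], end_frame = m[, 2])
}

# minimum periodic distance by enumerating all 27 images
oracle_min_image_dist <- function(x, y, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- y + c(ix, iy, iz) * box - x
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# best-fit RMSD by rotation search: random quaternion scan followed by
# direct Nelder-Mead minimization over Euler angles (no SVD anywhere)
oracle_superpose_rmsd <- function(mobile, reference, n_rot = 20000L) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  quat_matrix <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), nrow = 3, byrow = TRUE)
  }
  euler_matrix <- function(e) {
    cz <- cos(e[1]); sz <- sin(e[1])
    cy <- cos(e[2]); sy <- sin(e[2])
    cx <- cos(e[3]); sx <- sin(e[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  rmsd_of <- function(R) sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  best <- Inf
  best_q <- c(1, 0, 0, 0)
  for (i in seq_len(n_rot)) {
    q <- rnorm(4)
    r <- rmsd_of(quat_matrix(q))
    if (r < best) { best <- r; best_q <- q }
  }
  # polish: minimize over Euler angles from several starts near the best
  Rb <- quat_matrix(best_q)
  e0 <- c(atan2(Rb[2, 1], Rb[1, 1]), -asin(max(-1, min(1, Rb[3, 1]))),
          atan2(Rb[3, 2], Rb[3, 3]))
  for (start in list(e0, e0 + 0.05, e0 - 0.05)) {
    o <- stats::optim(start, function(e) rmsd_of(euler_matrix(e)),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# random rigid transform applied to an [n, 3] coordinate matrix
random_rigid_transform <- function(coords) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
  t <- rnorm(3, 0, 5)
  sweep(coords %*% t(R), 2, t, "+")
}

# small two-domain fixture for hinge/angle work: triplets plus filler beads
hinge_domains <- function() {
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, -0.3))
  B <- rbind(c(3, 0, 0), c(4, 0, 0), c(3, 1, 0), c(3.5, 0.4, 0.2))
  list(A = A, B = B)
}

# minimal in-memory system: one protein bead at the box center and one lipid
# bead whose per-frame position is supplied
probe_system <- function(lipid_xyz, box = c(10, 10, 10), dt = 1) {
  nf <- nrow(lipid_xyz)
  meta <- particle_meta(
    particle_index = 0:1,
    residue_id = c(1L, 100L),
    residue_name = c("ALA", "GM3"),
    segment_id = c("P", "L"),
    particle_name = c("BB", "HG"),
    category = c("protein", "lipid"),
    species = c("", "GM3")
  )
  coords <- array(0, dim = c(nf, 2L, 3L))
  coords[, 1L, ] <- matrix(box / 2, nf, 3, byrow = TRUE)
  coords[, 2L, ] <- lipid_xyz
  list(meta = meta,
       frames = frame_series(coords, times = (seq_len(nf) - 1) * dt, box = box))
}
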