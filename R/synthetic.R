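# Synthetic trajectory generators with exact ground truth.
#
# The binding generator encodes only the statistical structure the contact
# analyses assume: lipids diffuse laterally in one leaflet and bind labelled
# protein sites as a discrete-time two-state Markov chain with exact
# exponential transition probabilities per step (so dwell times are geometric
# with the correct continuous-time mean). Placement is constructed strictly
# inside/outside the dual-cutoff band: a bound headgroup sits < 0.45 nm from
# its site's residues, an unbound one >= 1.2 nm from every protein bead, so
# detection with the 0.55/1.0 nm rule recovers the Markov state exactly.

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a lipid-binding trajectory with known kinetics
#'
#' A static protein bead cloud carries labelled binding sites; each lipid
#' follows a per-site two-state Markov chain (unbound to bound with
#' probability `1 - exp(-k_on * dt)` per step, bound to unbound with
#' `1 - exp(-k_off * dt)`). Unbound lipids perform a reflected 2D random walk
#' in the leaflet plane. Every true bound interval is recorded in the returned
#' ground truth.
#'
#' @param n_lipids Number of lipid molecules (one headgroup bead each).
#' @param sites List of sites, each `list(residue_ids =, k_on =, k_off =)`
#'   with rates in 1/ns.
#' @param dt Frame spacing in ns.
#' @param n_frames Number of frames.
#' @param box Length-3 box (nm); default the 15 x 15 x 17 nm membrane-patch
#'   box used throughout.
#' @param seed Integer RNG seed (bit-identical output for equal seeds).
#' @param n_filler_residues Protein residues that are not part of any site,
#'   clustered at the protein center.
#' @param lipid_species Species label for the generated lipids.
#' @param site_radius Lateral distance (nm) of site clusters from the protein
#'   center; defaults to 0 for one site and 2 nm otherwise (keeps sites
#'   separated by more than the outer cutoff).
#' @param step_sd Per-frame Gaussian step (nm) of the unbound lateral walk.
#'   The default 1.5 nm is deliberately fast: the generator encodes
#'   statistical structure only, and the walk must decorrelate well within a
#'   few thousand frames for leaflet-uniformity properties to hold.
#' @return List with `meta`, `frames`, and `truth` (class
#'   `SyntheticGroundTruth`: per-site rates, site residue_ids, a data frame of
#'   true bound intervals, the seed, and the exclusion radius of the walk).
#' @export
make_binding_trajectory <- function(n_lipids, sites, dt, n_frames,
                                    box = c(15, 15, 17), seed = 1L,
                                    n_filler_residues = 0L,
                                    lipid_species = "GM3",
                                    site_radius = NULL, step_sd = 1.5) {
  lk_assert(dt > 0, "dt must be > 0")
  lk_assert(n_frames >= 1 && n_lipids >= 1, "need n_lipids >= 1, n_frames >= 1")
  lk_assert(length(sites) >= 1, "need at least one site")
  k_on <- vapply(sites, function(s) as.numeric(s$k_on), 0)
  k_off <- vapply(sites, function(s) as.numeric(s$k_off), 0)
  lk_assert(all(k_on >= 0) && all(k_off > 0), "rates must be positive (k_on may be 0)")
  if (any(k_off * dt > 0.2)) {
    lk_error(sprintf(
      "k_off * dt = %.3g exceeds 0.2; reduce dt so discretized kinetics track the continuous process",
      max(k_off * dt)), "lipidkin_rate_step_bound")
  }
  ns <- length(sites)
  site_resids <- lapply(sites, function(s) as.integer(s$residue_ids))
  protein_resids <- c(sort(unique(unlist(site_resids))),
                      if (n_filler_residues > 0L)
                        max(unlist(site_resids)) + seq_len(n_filler_residues))
  for (s in seq_len(ns)) {
    lk_assert(all(site_resids[[s]] %in% protein_resids),
              "site residue_ids must be protein residues")
  }
  if (is.null(site_radius)) site_radius <- if (ns > 1L) 2.0 else 0.0

  center <- c(box[1] / 2, box[2] / 2)
  z0 <- box[3] / 2
  # site cluster centers on a circle; residues of one site tightly clustered
  site_centers <- t(vapply(seq_len(ns), function(s) {
    a <- 2 * pi * (s - 1) / ns
    center + site_radius * c(cos(a), sin(a))
  }, numeric(2)))
  res_xy <- matrix(0, nrow = length(protein_resids), ncol = 2,
                   dimnames = list(protein_resids, NULL))
  for (s in seq_len(ns)) {
    rs <- site_resids[[s]]
    off <- 0.04 * cbind(cos(2 * pi * seq_along(rs) / length(rs)),
                        sin(2 * pi * seq_along(rs) / length(rs)))
    res_xy[as.character(rs), ] <- matrix(site_centers[s, ], nrow = length(rs),
                                         ncol = 2, byrow = TRUE) + off
  }
  if (n_filler_residues > 0L) {
    fill <- setdiff(protein_resids, unlist(site_resids))
    off <- 0.05 * cbind(cos(2 * pi * seq_along(fill) / length(fill)),
                        sin(2 * pi * seq_along(fill) / length(fill)))
    res_xy[as.character(fill), ] <- matrix(center, nrow = length(fill),
                                           ncol = 2, byrow = TRUE) + off
  }
  prot_lat <- sqrt(colSums((t(res_xy) - center)^2))
  r_excl <- max(prot_lat) + 1.2 + 0.1   # unbound lipids stay outside this disk

  np <- length(protein_resids)
  nl <- n_lipids
  lipid_resids <- 1000L + seq_len(nl)
  meta <- particle_meta(
    particle_index = seq_len(np + nl) - 1L,
    residue_id = c(protein_resids, lipid_resids),
    residue_name = c(rep("ALA", np), rep(lipid_species, nl)),
    segment_id = c(rep("P", np), rep("L", nl)),
    particle_name = c(rep("BB", np), rep("HG", nl)),
    category = c(rep("protein", np), rep("lipid", nl)),
    species = c(rep("", np), rep(lipid_species, nl))
  )

  p_on <- 1 - exp(-k_on * dt)
  p_off <- 1 - exp(-k_off * dt)

  out <- with_seed(seed, {
    coords <- array(0, dim = c(n_frames, np + nl, 3))
    coords[, seq_len(np), 1] <- matrix(res_xy[, 1], n_frames, np, byrow = TRUE)
    coords[, seq_len(np), 2] <- matrix(res_xy[, 2], n_frames, np, byrow = TRUE)
    coords[, seq_len(np), 3] <- z0

    # initial unbound positions: uniform over the box outside the exclusion disk
    lx <- runif(nl, 0, box[1]); ly <- runif(nl, 0, box[2])
    bad <- (lx - center[1])^2 + (ly - center[2])^2 < r_excl^2
    while (any(bad)) {
      lx[bad] <- runif(sum(bad), 0, box[1])
      ly[bad] <- runif(sum(bad), 0, box[2])
      bad <- (lx - center[1])^2 + (ly - center[2])^2 < r_excl^2
    }
    state <- integer(nl)            # 0 unbound, s > 0 bound to site s
    start_frame <- integer(nl)
    iv_lipid <- integer(0); iv_site <- integer(0)
    iv_start <- integer(0); iv_end <- integer(0)

    place_bound <- function(which_l) {
      s <- state[which_l]
      r <- 0.3 * sqrt(runif(length(which_l)))
      a <- runif(length(which_l), 0, 2 * pi)
      cbind(site_centers[s, 1] + r * cos(a), site_centers[s, 2] + r * sin(a))
    }

    for (f in seq_len(n_frames)) {
      if (f > 1L) {
        unb_prev <- which(state == 0L)   # unbound at f-1: the binding candidates
        # bound -> unbound
        bnd <- which(state > 0L)
        if (length(bnd) > 0L) {
          rel <- bnd[runif(length(bnd)) < p_off[state[bnd]]]
          for (l in rel) {
            iv_lipid <- c(iv_lipid, l); iv_site <- c(iv_site, state[l])
            iv_start <- c(iv_start, start_frame[l]); iv_end <- c(iv_end, f - 2L)
          }
          if (length(rel) > 0L) {
            # re-enter the walk just outside the exclusion disk
            a <- runif(length(rel), 0, 2 * pi)
            rr <- r_excl + 0.2 + 0.3 * runif(length(rel))
            lx[rel] <- center[1] + rr * cos(a)
            ly[rel] <- center[2] + rr * sin(a)
            state[rel] <- 0L
          }
        }
        # unbound -> bound (first site whose clock fires); lipids released in
        # this very step sit out one frame so truth intervals stay separated
        unb <- unb_prev
        if (length(unb) > 0L && any(p_on > 0)) {
          u <- matrix(runif(length(unb) * ns), ncol = ns)
          hit <- u < matrix(p_on, nrow = length(unb), ncol = ns, byrow = TRUE)
          first <- apply(hit, 1L, function(h) if (any(h)) which(h)[1] else 0L)
          newly <- unb[first > 0L]
          if (length(newly) > 0L) {
            state[newly] <- first[first > 0L]
            start_frame[newly] <- f - 1L
          }
        }
        # diffuse the (still) unbound: symmetric Gaussian proposal folded at
        # the box walls; proposals inside the protein exclusion disk are
        # rejected (walker stays put), which leaves the uniform measure on
        # the accessible leaflet exactly invariant
        unb <- which(state == 0L)
        if (length(unb) > 0L) {
          px <- lx[unb] + rnorm(length(unb), 0, step_sd)
          py <- ly[unb] + rnorm(length(unb), 0, step_sd)
          px <- abs(px); px <- box[1] - abs(box[1] - px)
          py <- abs(py); py <- box[2] - abs(box[2] - py)
          ok <- (px - center[1])^2 + (py - center[2])^2 >= r_excl^2
          lx[unb[ok]] <- px[ok]
          ly[unb[ok]] <- py[ok]
        }
      }
      bnd <- which(state > 0L)
      if (length(bnd) > 0L) {
        pos <- place_bound(bnd)
        lx[bnd] <- pos[, 1]; ly[bnd] <- pos[, 2]
      }
      coords[f, np + seq_len(nl), 1] <- lx
      coords[f, np + seq_len(nl), 2] <- ly
      coords[f, np + seq_len(nl), 3] <- z0
    }
    # close intervals still bound at the final frame (censored)
    open <- which(state > 0L)
    censored <- logical(length(iv_lipid))
    for (l in open) {
      iv_lipid <- c(iv_lipid, l); iv_site <- c(iv_site, state[l])
      iv_start <- c(iv_start, start_frame[l]); iv_end <- c(iv_end, n_frames - 1L)
      censored <- c(censored, TRUE)
    }
    intervals <- data.frame(
      lipid = sprintf("L/%d", lipid_resids[iv_lipid]),
      site = iv_site,
      start_frame = iv_start,
      end_frame = iv_end,
      censored = censored,
      stringsAsFactors = FALSE
    )
    intervals$duration_ns <- (intervals$end_frame - intervals$start_frame + 1) * dt
    ord <- order(intervals$lipid, intervals$start_frame)
    list(coords = coords, intervals = intervals[ord, , drop = FALSE])
  })

  frames <- frame_series(out$coords, times = (seq_len(n_frames) - 1) * dt,
                         box = box)
  truth <- structure(list(
    k_on = k_on, k_off = k_off, site_residue_ids = site_resids,
    intervals = out$intervals, rng_seed = as.integer(seed), dt = dt,
    exclusion_radius = r_excl, protein_center = center,
    angle_series = NULL
  ), class = "SyntheticGroundTruth")
  list(meta = meta, frames = frames, truth = truth)
}

#' Generate a two-domain hinge trajectory with a prescribed plane angle
#'
#' Domain A stays fixed; domain B is rigidly rotated per frame about a fixed
#' hinge axis so that the oriented inter-plane angle (the
#' [interdomain_angle()] convention) equals `angle_series` exactly. The first
#' three points of each domain are its plane-defining triplet.
#'
#' @param domainA_points,domainB_points Numeric matrices `[>=3, 3]` (nm); rows
#'   1:3 define each plane. Additional rows are filler beads.
#' @param angle_series Per-frame angles in degrees, each in `[0, 180]`.
#' @param dt Frame spacing (ns).
#' @param seed RNG seed (used only when `jitter_sd > 0`).
#' @param jitter_sd Isotropic Gaussian jitter (nm) added to filler beads only.
#' @param hinge_point Point the hinge axis passes through; default the
#'   centroid of domain B's triplet.
#' @return List with `meta`, `frames`, `truth` (`SyntheticGroundTruth` with
#'   `angle_series`).
#' @export
make_hinge_trajectory <- function(domainA_points, domainB_points, angle_series,
                                  dt = 0.1, seed = 1L, jitter_sd = 0,
                                  hinge_point = NULL) {
  domainA_points <- as.matrix(domainA_points)
  domainB_points <- as.matrix(domainB_points)
  lk_assert(nrow(domainA_points) >= 3L && nrow(domainB_points) >= 3L &&
              ncol(domainA_points) == 3L && ncol(domainB_points) == 3L,
            "domains must be [>=3, 3] matrices")
  lk_assert(all(angle_series >= 0 & angle_series <= 180),
            "angle_series values must lie in [0, 180] degrees")
  nA <- triplet_normal(domainA_points[1:3, ])
  nB <- triplet_normal(domainB_points[1:3, ])
  if (is.null(hinge_point)) hinge_point <- colMeans(domainB_points[1:3, ])

  # pre-align B so its triplet normal coincides with A's (angle 0 reference)
  R0 <- rotation_between(nB, nA)
  B0 <- sweep(sweep(domainB_points, 2, hinge_point) %*% t(R0), 2, hinge_point, "+")
  # hinge axis: any unit vector perpendicular to A's normal
  u <- pick_perpendicular(nA)

  nf <- length(angle_series)
  npts <- nrow(domainA_points) + nrow(domainB_points)
  coords <- array(0, dim = c(nf, npts, 3))
  out <- with_seed(seed, {
    for (f in seq_len(nf)) {
      R <- axis_angle_matrix(u, angle_series[f] * pi / 180)
      Bf <- sweep(sweep(B0, 2, hinge_point) %*% t(R), 2, hinge_point, "+")
      if (jitter_sd > 0 && nrow(Bf) > 3L) {
        fill <- 4:nrow(Bf)
        Bf[fill, ] <- Bf[fill, ] + matrix(rnorm(length(fill) * 3, 0, jitter_sd),
                                          ncol = 3)
      }
      Af <- domainA_points
      if (jitter_sd > 0 && nrow(Af) > 3L) {
        fill <- 4:nrow(Af)
        Af[fill, ] <- Af[fill, ] + matrix(rnorm(length(fill) * 3, 0, jitter_sd),
                                          ncol = 3)
      }
      coords[f, , ] <- rbind(Af, Bf)
    }
    coords
  })
  nAp <- nrow(domainA_points); nBp <- nrow(domainB_points)
  meta <- particle_meta(
    particle_index = seq_len(npts) - 1L,
    residue_id = c(seq_len(nAp), 100L + seq_len(nBp)),
    residue_name = rep("ALA", npts),
    segment_id = rep("A", npts),
    particle_name = rep("CA", npts),
    category = rep("protein", npts),
    species = rep("", npts)
  )
  frames <- frame_series(out, times = (seq_len(nf) - 1) * dt, box = c(50, 50, 50))
  truth <- structure(list(
    k_on = NULL, k_off = NULL, site_residue_ids = NULL, intervals = NULL,
    rng_seed = as.integer(seed), dt = dt, angle_series = as.numeric(angle_series)
  ), class = "SyntheticGroundTruth")
  list(meta = meta, frames = frames, truth = truth)
}

#' Sample contact durations from a bi-exponential mixture
#'
#' Draws i.i.d. durations from
#' `amplitude_fast * Exp(k_fast) + (1 - amplitude_fast) * Exp(k_slow)`,
#' the model family fitted by [fit_koff()].
#'
#' @param amplitude_fast Mixture weight of the fast component, in `[0, 1]`.
#' @param k_fast,k_slow Rates in 1/ns with `k_fast >= k_slow > 0`.
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return Numeric vector of `n` durations (ns).
#' @export
sample_durations <- function(amplitude_fast, k_fast, k_slow, n, seed = 1L) {
  lk_assert(amplitude_fast >= 0 && amplitude_fast <= 1,
            "amplitude_fast must lie in [0, 1]")
  lk_assert(k_fast >= k_slow && k_slow > 0,
            "need k_fast >= k_slow > 0")
  lk_assert(is_count(n) && n >= 1, "n must be a positive integer")
  with_seed(seed, {
    fast <- stats::runif(n) < amplitude_fast
    ifelse(fast, stats::rexp(n, k_fast), stats::rexp(n, k_slow))
  })
}
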