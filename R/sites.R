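# Binding-site occupancy time series and lateral radial distribution of lipid
# species around a reference (typically the transmembrane domain).

#' Declare a binding site
#'
#' @param label Site name (e.g. `"site 1"`).
#' @param residue_ids Protein residues forming the site.
#' @param cutoff Probe cutoff in nm; default 0.6 nm (6 Angstrom), the standard
#'   occupancy cutoff for both coarse-grained and atomistic systems.
#' @return A `BindingSite` list.
#' @export
binding_site <- function(label, residue_ids, cutoff = 0.6) {
  lk_assert(length(residue_ids) >= 1L, "site needs at least one residue")
  lk_assert(cutoff > 0, "cutoff must be > 0")
  structure(list(label = label, residue_ids = as.integer(residue_ids),
                 cutoff = cutoff), class = "BindingSite")
}

#' Site occupancy time series
#'
#' Counts, per frame, the selected lipid headgroup particles within the site
#' cutoff (minimum-image) of any site-residue particle. The normalized series
#' divides by the maximal raw count (all zeros stay zero), matching the
#' white-to-black occupancy convention of normalized site plots.
#'
#' @param frames A [frame_series()].
#' @param meta A [particle_meta()].
#' @param site A [binding_site()].
#' @param lipid_selection Selection expression or 0-based particle indices of
#'   the probing headgroup particles.
#' @return An `OccupancySeries` data frame (frame, time_ns, raw, normalized).
#' @export
site_occupancy <- function(frames, meta, site, lipid_selection) {
  check_system(meta, frames)
  lk_assert(inherits(site, "BindingSite"), "need a BindingSite")
  site_idx <- meta$particle_index[meta$residue_id %in% site$residue_ids &
                                    meta$category == "protein"]
  if (length(site_idx) == 0L) {
    lk_error(sprintf("site '%s' resolves to no protein particles", site$label),
             "lipidkin_empty_selection")
  }
  lip_idx <- as_indices(meta, lipid_selection)
  nf <- frames$n_frames
  P <- frames$coordinates[, site_idx + 1L, , drop = FALSE]
  cut2 <- site$cutoff^2
  raw <- integer(nf)
  for (b in lip_idx) {
    Lb <- frames$coordinates[, b + 1L, , drop = TRUE]
    if (nf == 1L) Lb <- matrix(Lb, nrow = 1L)
    D2 <- 0
    for (k in 1:3) {
      dk <- min_image(P[, , k] - Lb[, k], frames$box[, k])
      D2 <- D2 + dk * dk
    }
    D2 <- matrix(D2, nrow = nf)
    m <- D2[, 1]
    for (cc in seq_len(ncol(D2))[-1]) m <- pmin(m, D2[, cc])
    raw <- raw + as.integer(m < cut2)
  }
  normalized <- if (max(raw) > 0) raw / max(raw) else rep(0, nf)
  structure(data.frame(frame = seq_len(nf) - 1L, time_ns = frames$times,
                       raw = raw, normalized = normalized),
            class = c("OccupancySeries", "data.frame"),
            site = site$label, cutoff = site$cutoff)
}

#' Lateral radial distribution function around a reference selection
#'
#' For each frame, measures the lateral (xy, minimum-image) distance from each
#' selected species headgroup particle to the xy center of geometry of the
#' reference selection, histograms them in uniform bins, and normalizes by
#' annulus area `2 pi r dr`, frame count, and the mean lateral number density
#' of the species in the leaflet — so a uniformly distributed species gives
#' `g(r) ~ 1` at large r.
#'
#' @param frames A [frame_series()].
#' @param meta A [particle_meta()].
#' @param reference_selection Selection for the reference (e.g. the
#'   transmembrane domain).
#' @param species_selection Selection for the species headgroup particles.
#' @param r_max Largest distance (nm); must not exceed half the smallest
#'   lateral box length.
#' @param n_bins Number of uniform bins.
#' @param z_range Optional `c(z_min, z_max)` (nm) leaflet filter applied to
#'   the species particles per frame.
#' @return A `RadialProfile` data frame (r, g, counts) with attributes
#'   `bin_width` and `total_observations` (pair observations within `r_max`).
#' @export
lateral_rdf <- function(frames, meta, reference_selection, species_selection,
                        r_max, n_bins = 50L, z_range = NULL) {
  check_system(meta, frames)
  ref_idx <- as_indices(meta, reference_selection)
  sp_idx <- as_indices(meta, species_selection)
  lk_assert(length(ref_idx) > 0L && length(sp_idx) > 0L,
            "empty reference or species selection")
  half_min <- min(frames$box[, 1:2]) / 2
  if (r_max > half_min + 1e-12) {
    lk_error(sprintf(
      "r_max = %.3g nm exceeds half the smallest lateral box length (%.3g nm)",
      r_max, half_min), "lipidkin_rmax_too_large")
  }
  nf <- frames$n_frames
  breaks <- seq(0, r_max, length.out = n_bins + 1L)
  dr <- breaks[2] - breaks[1]
  counts <- integer(n_bins)
  n_obs_total <- 0          # species particles in the leaflet (density basis)
  area_sum <- 0
  for (f in seq_len(nf)) {
    xy <- matrix(frames$coordinates[f, , 1:2], ncol = 2L)
    refc <- colMeans(xy[ref_idx + 1L, , drop = FALSE])
    sp <- sp_idx
    if (!is.null(z_range)) {
      z <- frames$coordinates[f, sp + 1L, 3]
      sp <- sp[z >= z_range[1] & z <= z_range[2]]
    }
    if (length(sp) == 0L) next
    n_obs_total <- n_obs_total + length(sp)
    area_sum <- area_sum + frames$box[f, 1] * frames$box[f, 2]
    dx <- min_image(xy[sp + 1L, 1] - refc[1], frames$box[f, 1])
    dy <- min_image(xy[sp + 1L, 2] - refc[2], frames$box[f, 2])
    r <- sqrt(dx^2 + dy^2)
    r <- r[r < r_max]
    if (length(r) > 0L) {
      bins <- pmin(floor(r / dr) + 1L, n_bins)
      tab <- tabulate(bins, nbins = n_bins)
      counts <- counts + tab
    }
  }
  lk_assert(n_obs_total > 0, "species never present in the requested leaflet")
  density <- n_obs_total / area_sum          # mean lateral number density
  centers <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  g <- counts / (nf * 2 * pi * centers * dr * density)
  structure(data.frame(r = centers, g = g, counts = counts),
            class = c("RadialProfile", "data.frame"),
            bin_width = dr, total_observations = sum(counts),
            density = density)
}
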