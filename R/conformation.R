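# Domain-conformation metrics: inter-domain plane angle, least-squares
# superposition, domain RMSD relative to frame 0, and trajectory PCA.

# --- geometry helpers -------------------------------------------------------

#' @keywords internal
#' @noRd
triplet_normal <- function(pts) {
  v1 <- pts[2, ] - pts[1, ]
  v2 <- pts[3, ] - pts[1, ]
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) {
    lk_error("collinear plane triplet (cross-product norm < 1e-9 nm^2)",
             "lipidkin_collinear_triplet")
  }
  n / nn
}

#' @keywords internal
#' @noRd
axis_angle_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# rotation taking unit vector a onto unit vector b
#' @keywords internal
#' @noRd
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2))
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    return(axis_angle_matrix(pick_perpendicular(a), pi))
  }
  axis_angle_matrix(v / s, atan2(s, cth))
}

#' @keywords internal
#' @noRd
pick_perpendicular <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- c(n[2] * ref[3] - n[3] * ref[2], n[3] * ref[1] - n[1] * ref[3],
         n[1] * ref[2] - n[2] * ref[1])
  v / sqrt(sum(v^2))
}

# --- plane spec -------------------------------------------------------------

#' Define the two plane triplets for the inter-domain angle
#'
#' Each domain's plane is spanned by three particles given as ordered residue
#' ids; the plane normal's orientation follows that order (right-hand rule),
#' so reported angles live on the full `[0, 180]` degree range without folding.
#' The canonical receptor usage picks the backbone bead (coarse-grained) or
#' the C-alpha atom (atomistic) of each residue.
#'
#' @param domain1_residues,domain2_residues Ordered integer triplets of
#'   residue ids.
#' @param particle_rule `"backbone_bead"` (particle name `BB`) or `"CA"`.
#' @return A `PlaneSpec` list.
#' @export
plane_spec <- function(domain1_residues, domain2_residues,
                       particle_rule = c("backbone_bead", "CA")) {
  particle_rule <- match.arg(particle_rule)
  lk_assert(length(domain1_residues) == 3L && length(domain2_residues) == 3L,
            "each domain needs an ordered triplet of residue ids")
  structure(list(domain1_residues = as.integer(domain1_residues),
                 domain2_residues = as.integer(domain2_residues),
                 particle_rule = particle_rule),
            class = "PlaneSpec")
}

#' @keywords internal
#' @noRd
resolve_triplet <- function(meta, resids, particle_rule) {
  pname <- if (particle_rule == "backbone_bead") "BB" else "CA"
  idx <- vapply(resids, function(r) {
    hits <- meta$particle_index[meta$residue_id == r &
                                  meta$particle_name == pname &
                                  meta$category == "protein"]
    if (length(hits) == 0L) {
      # fall back to the residue's first particle (single-bead fixtures)
      hits <- meta$particle_index[meta$residue_id == r & meta$category == "protein"]
    }
    lk_assert(length(hits) >= 1L,
              sprintf("plane residue %d does not resolve to a particle", r))
    hits[1]
  }, integer(1))
  idx
}

# --- operations -------------------------------------------------------------

#' Inter-domain plane angle per frame
#'
#' For each frame, takes the oriented normal of each domain's ordered triplet
#' `(P1, P2, P3)` as `normalize((P2 - P1) x (P3 - P1))` and reports
#' `acos(clamp(n1 . n2, -1, 1))` in degrees. Frames with a collinear triplet
#' are excluded and recorded in the `errors` attribute.
#'
#' @param frames A [frame_series()].
#' @param spec A [plane_spec()].
#' @param meta A [particle_meta()] used to resolve the triplets.
#' @return An `AngleSeries`: data.frame (frame, time_ns, angle_deg) with
#'   `mean` / `sd` attributes.
#' @export
interdomain_angle <- function(frames, spec, meta) {
  i1 <- resolve_triplet(meta, spec$domain1_residues, spec$particle_rule)
  i2 <- resolve_triplet(meta, spec$domain2_residues, spec$particle_rule)
  nf <- frames$n_frames
  ang <- rep(NA_real_, nf)
  errs <- integer(0)
  for (f in seq_len(nf)) {
    p <- matrix(frames$coordinates[f, , ], ncol = 3L)
    n1 <- try(triplet_normal(p[i1 + 1L, , drop = FALSE]), silent = TRUE)
    n2 <- try(triplet_normal(p[i2 + 1L, , drop = FALSE]), silent = TRUE)
    if (inherits(n1, "try-error") || inherits(n2, "try-error")) {
      errs <- c(errs, f - 1L)
      next
    }
    ang[f] <- acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
  }
  if (length(errs) > 0L) {
    warning(sprintf("%d frame(s) with collinear plane triplets excluded",
                    length(errs)), call. = FALSE)
  }
  keep <- !is.na(ang)
  out <- data.frame(frame = which(keep) - 1L, time_ns = frames$times[keep],
                    angle_deg = ang[keep])
  structure(out, class = c("AngleSeries", "data.frame"),
            mean = mean(out$angle_deg), sd = stats::sd(out$angle_deg),
            errors = errs)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimizing the RMSD of
#' `mobile[fit_idx, ]` onto `reference[fit_idx, ]`, and applies it to all
#' mobile coordinates.
#'
#' @param mobile,reference `[n, 3]` coordinate matrices (nm).
#' @param fit_idx Row indices (1-based) used for the fit; default all rows.
#' @return List with `coordinates` (transformed mobile), `rotation` (3x3),
#'   `translation` (length 3, applied after rotation about the fit centroid)
#'   and `rmsd` over the fit selection (nm).
#' @export
superpose <- function(mobile, reference, fit_idx = seq_len(nrow(mobile))) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  lk_assert(length(fit_idx) >= 3L, "need >= 3 fit particles")
  A <- mobile[fit_idx, , drop = FALSE]
  B <- reference[fit_idx, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- sweep(sweep(mobile, 2, ca) %*% t(R), 2, cb, "+")
  fitted <- moved[fit_idx, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(coordinates = moved, rotation = R, translation = cb - c(R %*% ca),
       rmsd = rmsd)
}

#' Per-frame RMSD of a selection after superposition on a fit selection
#'
#' Every frame is superposed on frame 0 using `fit_selection`; the RMSD is
#' then computed over `rmsd_selection` only. The canonical receptor usage fits
#' on the transmembrane domain and measures the extracellular domain.
#'
#' @param frames A [frame_series()].
#' @param meta A [particle_meta()].
#' @param fit_selection,rmsd_selection Selection expressions (see
#'   [resolve_selection()]) or integer vectors of 0-based particle indices.
#' @return Data frame (frame, time_ns, rmsd_nm).
#' @export
domain_rmsd <- function(frames, meta, fit_selection, rmsd_selection) {
  fit <- as_indices(meta, fit_selection) + 1L
  msr <- as_indices(meta, rmsd_selection) + 1L
  ref <- matrix(frames$coordinates[1, , ], ncol = 3L)
  out <- vapply(seq_len(frames$n_frames), function(f) {
    mob <- matrix(frames$coordinates[f, , ], ncol = 3L)
    sup <- superpose(mob, ref, fit_idx = fit)
    sqrt(mean(rowSums((sup$coordinates[msr, , drop = FALSE] -
                         ref[msr, , drop = FALSE])^2)))
  }, numeric(1))
  data.frame(frame = seq_len(frames$n_frames) - 1L, time_ns = frames$times,
             rmsd_nm = out)
}

#' @keywords internal
#' @noRd
as_indices <- function(meta, sel) {
  if (is.character(sel)) resolve_selection(meta, sel) else as.integer(sel)
}

#' Principal component analysis of fitted trajectory coordinates
#'
#' Frames are superposed on frame 0 via `fit_selection`; the covariance of the
#' flattened `analysis_selection` coordinates about their time mean is
#' eigen-decomposed. `fraction_first` is the share of total positional
#' variance carried by the first component, the headline number of the
#' domain-motion analysis.
#'
#' @param frames A [frame_series()].
#' @param meta A [particle_meta()].
#' @param fit_selection,analysis_selection Selections (expression or 0-based
#'   indices).
#' @param n_components Number of eigenvectors to retain (default 10).
#' @return A `PCAResult` list: `mean` (3N), `eigenvalues` (nm^2, all of them),
#'   `eigenvectors` (3N x k), `fraction_first`, `projections` (frames x k,
#'   nm), `extremes` (two 3N rows: mean +/- range along component 1),
#'   `total_variance`.
#' @export
trajectory_pca <- function(frames, meta, fit_selection, analysis_selection,
                           n_components = 10L) {
  fit <- as_indices(meta, fit_selection) + 1L
  ana <- as_indices(meta, analysis_selection) + 1L
  nf <- frames$n_frames
  if (nf <= 3L * length(ana)) {
    warning(sprintf(
      "only %d frames for %d analysis particles; covariance will be rank-deficient",
      nf, length(ana)), call. = FALSE)
  }
  ref <- matrix(frames$coordinates[1, , ], ncol = 3L)
  X <- matrix(0, nrow = nf, ncol = 3L * length(ana))
  for (f in seq_len(nf)) {
    mob <- matrix(frames$coordinates[f, , ], ncol = 3L)
    sup <- superpose(mob, ref, fit_idx = fit)
    X[f, ] <- as.vector(t(sup$coordinates[ana, , drop = FALSE]))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total_var <- sum(Xc^2) / (nf - 1L)
  if (total_var <= 0 || !is.finite(total_var)) {
    lk_error("no motion to analyze (zero total variance)", "lipidkin_no_motion")
  }
  # eigen-decompose via SVD of the centered data matrix (stable, and cheap in
  # whichever of n_frames / 3N is smaller)
  sv <- svd(Xc, nu = 0, nv = min(dim(Xc)))
  lambda <- sv$d^2 / (nf - 1L)
  k <- min(n_components, length(lambda))
  vecs <- sv$v[, seq_len(k), drop = FALSE]
  proj <- Xc %*% vecs
  range1 <- range(proj[, 1])
  extremes <- rbind(mu + vecs[, 1] * range1[1], mu + vecs[, 1] * range1[2])
  structure(list(
    mean = mu, eigenvalues = lambda, eigenvectors = vecs,
    fraction_first = lambda[1] / sum(lambda), projections = proj,
    extremes = extremes, total_variance = total_var,
    analysis_indices = ana - 1L
  ), class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf(
    "PCAResult: %d eigenvalues, first = %.4g nm^2 (%.1f%% of total variance)\n",
    length(x$eigenvalues), x$eigenvalues[1], 100 * x$fraction_first))
  invisible(x)
}
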