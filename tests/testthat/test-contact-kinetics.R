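# Dual-cutoff detection, survival curves, and k_off fitting.

cg_spec <- function(grouping = "whole_protein") {
  contact_spec(resolution = "cg", grouping = grouping)
}

test_that("minimum-image distances match direct and wrapped cases", {
  # lipid at origin-side positions vs a protein bead at the box center
  sys <- probe_system(rbind(c(5.3, 5, 5),    # 0.3 nm direct
                            c(9.8, 5, 5)),   # wraps: protein at 5 -> 5.2 nm? no
                      box = c(10, 10, 10))
  ds <- min_distance_series(sys$frames, sys$meta, "category lipid",
                            grouping = "whole_protein")
  expect_equal(ds$dist[1, 1, 1], 0.3, tolerance = 1e-12)
  # explicit wrap case: particles at x = 9.8 and 0.1 with 10 nm box
  sys2 <- probe_system(rbind(c(9.8, 0, 0)), box = c(10, 10, 10))
  sys2$frames$coordinates[1, 1, ] <- c(0.1, 0, 0)
  ds2 <- min_distance_series(sys2$frames, sys2$meta, "category lipid",
                             grouping = "whole_protein")
  expect_equal(ds2$dist[1, 1, 1], 0.3, tolerance = 1e-12)
})

test_that("min_distance_series equals the 27-image brute-force oracle", {
  set.seed(21)
  np <- 10L; nl <- 10L
  box <- c(4, 5, 6)
  meta <- particle_meta(
    particle_index = seq_len(np + nl) - 1L,
    residue_id = c(seq_len(np), 100L + seq_len(nl)),
    residue_name = c(rep("ALA", np), rep("GM3", nl)),
    segment_id = c(rep("P", np), rep("L", nl)),
    particle_name = c(rep("BB", np), rep("HG", nl)),
    category = c(rep("protein", np), rep("lipid", nl)),
    species = c(rep("", np), rep("GM3", nl)))
  coords <- array(0, dim = c(2, np + nl, 3))
  for (k in 1:3) coords[, , k] <- runif(2 * (np + nl), 0, box[k])
  frames <- frame_series(coords, c(0, 1), box)
  ds <- min_distance_series(frames, meta, "category lipid",
                            grouping = "residue")
  for (f in 1:2) for (li in seq_len(nl)) for (r in seq_len(np)) {
    d_oracle <- oracle_min_image_dist(coords[f, np + li, ], coords[f, r, ], box)
    expect_equal(ds$dist[f, li, r], d_oracle, tolerance = 1e-10)
  }
})

test_that("dual-cutoff automaton follows the stated entry/exit rules", {
  # enters below 0.55, survives to 0.95, exits above 1.0
  ev <- detect_contacts(c(0.50, 0.80, 0.95, 1.05), cg_spec())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 0L)
  expect_equal(ev$end_frame, 2L)
  expect_equal(ev$duration_ns, 3)

  # 0.60 does not initiate; two separate events
  ev2 <- detect_contacts(c(0.60, 0.50, 1.20, 0.54, 0.90, 1.10), cg_spec())
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$start_frame, c(1L, 3L))
  expect_equal(ev2$end_frame, c(1L, 4L))

  # never below d_on: nothing
  expect_equal(nrow(detect_contacts(c(1.2, 1.4, 1.01), cg_spec())), 0L)

  # still bound at the end: closed there, flagged censored
  ev3 <- detect_contacts(c(0.9, 0.4, 0.8, 0.9), cg_spec())
  expect_equal(ev3$end_frame, 3L)
  expect_true(ev3$censored)
})

test_that("automaton equals the per-frame oracle on random series", {
  set.seed(22)
  for (i in 1:100) {
    d <- runif(200, 0, 1.5)
    ev <- detect_contacts(d, cg_spec())
    orc <- oracle_contacts(d, 0.55, 1.0)
    expect_equal(ev$start_frame, orc$start_frame)
    expect_equal(ev$end_frame, orc$end_frame)
  }
})

test_that("cutoff monotonicity: d_on grows contacts, d_off shrinks events", {
  set.seed(23)
  for (i in 1:20) {
    d <- runif(300, 0, 1.5)
    frames_at <- function(d_on, d_off) {
      ev <- detect_contacts(d, contact_spec(d_on, d_off, "whole_protein"))
      sum(ev$end_frame - ev$start_frame + 1L)
    }
    expect_lte(frames_at(0.4, 1.0), frames_at(0.6, 1.0))
    n_events <- function(d_off) {
      nrow(detect_contacts(d, contact_spec(0.55, d_off, "whole_protein")))
    }
    expect_gte(n_events(0.8), n_events(1.2))
  }
})

test_that("survival curve matches its definition on fixed durations", {
  sc <- survival_curve(c(2, 2, 4), max_lag = 5, n_points = 6L)
  expect_equal(sc$t_ns, 0:5)
  expect_equal(sc$sigma, c(1, 1, 1, 1 / 3, 1 / 3, 0))
  expect_equal(attr(sc, "n_events"), 3L)

  sc1 <- survival_curve(3.5, max_lag = 6, n_points = 7L)
  expect_equal(sc1$sigma, c(1, 1, 1, 1, 0, 0, 0))

  expect_error(survival_curve(numeric(0)), class = "lipidkin_no_events")
})

test_that("empirical survival of exponential draws tracks exp(-k t)", {
  d <- sample_durations(1, 0.5, 0.5, 10000, seed = 31)
  sc <- survival_curve(d, max_lag = 6, n_points = 61L)
  expect_lt(max(abs(sc$sigma - exp(-0.5 * sc$t_ns))), 0.02)
})

test_that("fit recovers a noiseless mono-exponential decay", {
  t <- seq(0, 50, length.out = 200)
  curve <- structure(data.frame(t_ns = t, sigma = exp(-0.1 * t)),
                     class = c("SurvivalCurve", "data.frame"),
                     n_events = 1000L, mean_duration = 10)
  fit <- fit_koff(curve)
  expect_true(fit$converged)
  expect_equal(fit$k_slow, 0.1, tolerance = 1e-3)
  expect_equal(fit$residence_time_ns, 10, tolerance = 1e-2)
  # degenerate amplitude allowed: either A ~ 0 or both rates ~ 0.1
  expect_true(fit$amplitude_fast < 0.05 || abs(fit$k_fast - 0.1) < 1e-2)
})

test_that("bi-exponential parameter recovery over repeated seeds", {
  ks <- numeric(10); kf <- numeric(10)
  for (s in 1:10) {
    d <- sample_durations(0.7, 1.0, 0.05, 5000, seed = s)
    fit <- fit_koff(survival_curve(d, max_lag = 60, n_points = 600L))
    ks[s] <- fit$k_slow; kf[s] <- fit$k_fast
  }
  expect_lt(abs(median(ks) - 0.05) / 0.05, 0.2)
  expect_lt(abs(median(kf) - 1.0) / 1.0, 0.3)
})

test_that("degenerate step survival is reported, not raised", {
  sc <- survival_curve(rep(4, 50), max_lag = 8, n_points = 20L)
  fit <- fit_koff(sc)
  expect_true(is.finite(fit$ssr))
  expect_true(!fit$converged || fit$ssr > 1e-3)
})

test_that("too few usable grid points is a structured error", {
  t <- seq(0, 5, length.out = 10)
  sig <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  curve <- structure(data.frame(t_ns = t, sigma = sig),
                     class = c("SurvivalCurve", "data.frame"),
                     n_events = 3L, mean_duration = 1)
  expect_error(fit_koff(curve), class = "lipidkin_insufficient_curve")
})

test_that("residue profile: zeros without events, censored full-span contact", {
  ev0 <- detect_contacts(rep(2, 10), cg_spec())
  prof0 <- residue_profile(ev0, n_frames = 10L, dt = 1,
                           residues = "target")
  expect_equal(prof0$residence_time_ns, 0)
  expect_equal(prof0$occupancy, 0)
  expect_equal(prof0$n_events, 0L)

  ev1 <- detect_contacts(rep(0.4, 20), cg_spec())
  prof1 <- residue_profile(ev1, n_frames = 20L, dt = 1)
  expect_equal(prof1$occupancy, 1.0)
  expect_equal(prof1$n_events, 1L)
  expect_true(ev1$censored)
  expect_false(prof1$fitted)    # single event: mean duration reported
  expect_equal(prof1$residence_time_ns, 20)
})

test_that("per-residue residence times separate fast and slow sites", {
  # pooled over several seeds of small systems; detection grouped by residue
  dur_a <- c(); dur_b <- c()
  ev_all <- list(); nf_tot <- 0L
  for (s in 1:10) {
    sim <- make_binding_trajectory(
      20, sites = list(list(residue_ids = 1:2, k_on = 0.08, k_off = 0.5),
                       list(residue_ids = 11:12, k_on = 0.08, k_off = 0.05)),
      dt = 0.1, n_frames = 3000, seed = 100 + s)
    ds <- min_distance_series(sim$frames, sim$meta, "category lipid",
                              grouping = "residue")
    ev <- detect_contacts(ds, cg_spec("residue"))
    ev_all[[s]] <- ev
    nf_tot <- nf_tot + sim$frames$n_frames
  }
  ev <- do.call(rbind, ev_all)
  prof <- residue_profile(ev, n_frames = nf_tot, dt = 0.1)
  rt_a <- prof$residence_time_ns[prof$target == "1"]
  rt_b <- prof$residence_time_ns[prof$target == "11"]
  expect_gt(rt_b, rt_a)
  expect_lt(abs(rt_a - 2) / 2, 0.2)
  expect_lt(abs(rt_b - 20) / 20, 0.2)
})

test_that("contact spec validates cutoffs and presets", {
  expect_equal(contact_spec(resolution = "cg")$d_on, 0.55)
  expect_equal(contact_spec(resolution = "cg")$d_off, 1.0)
  expect_equal(contact_spec(resolution = "at")$d_on, 0.35)
  expect_equal(contact_spec(resolution = "at")$d_off, 0.55)
  expect_equal(contact_spec(0.4, 0.9, resolution = "cg")$d_on, 0.4)
  expect_error(contact_spec(1.1, 0.9))
})
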