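# Pipeline orchestration: one config, many replicates, stage outputs as
# CSV/JSON plus a manifest. All stages are deterministic given the config;
# the seed is recorded in the manifest regardless.

#' Load and validate a run configuration
#'
#' The configuration is a single JSON file (one human-readable structured
#' text file); every value can also be supplied directly as a list. Validation
#' checks paths and fills cutoff defaults from the resolution preset
#' (`cg`: 0.55/1.0 nm, `at`: 0.35/0.55 nm) unless overridden.
#'
#' @param config Path to a JSON config or a named list.
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    lk_assert(file.exists(config), sprintf("config file not found: %s", config),
              "lipidkin_validation")
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  }
  lk_assert(is.list(config), "config must be a list or a JSON file path",
            "lipidkin_validation")
  lk_assert(!is.null(config$topology), "config needs `topology`",
            "lipidkin_validation")
  if (!file.exists(config$topology)) {
    lk_error(sprintf("topology path does not exist: %s", config$topology),
             "lipidkin_validation")
  }
  config$trajectories <- as.character(config$trajectories %||% character(0))
  for (p in config$trajectories) {
    if (!file.exists(p)) {
      lk_error(sprintf("trajectory path does not exist: %s", p),
               "lipidkin_validation")
    }
  }
  resolution <- config$resolution %||% "cg"
  preset <- if (identical(resolution, "at")) c(0.35, 0.55) else c(0.55, 1.0)
  config$resolution <- resolution
  config$d_on <- config$cutoffs$d_on %||% preset[1]
  config$d_off <- config$cutoffs$d_off %||% preset[2]
  config$grouping <- config$grouping %||% "residue"
  config$lipid_selection <- config$lipid_selection %||% "category lipid"
  config$protein_selection <- config$protein_selection %||% "category protein"
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% "lipidkin_out"
  config$species_map <- config$species_map %||% list()
  structure(config, class = "RunConfig")
}

#' @keywords internal
#' @noRd
stage_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run analysis stages over all replicates
#'
#' Executes the requested stages over every trajectory in the config, pooling
#' contact durations across replicates for the kinetic fits (per-replicate
#' fits via `per_replicate = TRUE`). Writes a manifest plus one CSV/JSON per
#' stage into `config$output_dir`, and returns the result bundle invisibly
#' rerunnable to bit-identical outputs.
#'
#' @param config A [run_config()] (or path / list accepted by it).
#' @param stages Subset of `c("contacts", "kinetics", "occupancy", "rdf",
#'   "angle", "rmsd", "pca")`.
#' @param per_replicate Also fit kinetics per replicate (diagnostics).
#' @return A `ReportBundle` list, invisibly.
#' @export
run_pipeline <- function(config, stages, per_replicate = FALSE) {
  config <- run_config(config)
  all_stages <- c("contacts", "kinetics", "occupancy", "rdf", "angle",
                  "rmsd", "pca")
  lk_assert(all(stages %in% all_stages),
            sprintf("unknown stage(s): %s",
                    paste(setdiff(stages, all_stages), collapse = ", ")),
            "lipidkin_validation")
  if ("kinetics" %in% stages && !("contacts" %in% stages)) {
    lk_error("stage 'kinetics' requires stage 'contacts' (pooled durations)",
             "lipidkin_validation")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  species_map <- lapply(config$species_map, function(s) {
    list(species = s$species, headgroups = as.character(s$headgroups %||% character(0)))
  })
  paths <- if (length(config$trajectories) > 0L) config$trajectories else NA_character_
  replicates <- lapply(paths, function(p) {
    load_system(config$topology, if (is.na(p)) NULL else p,
                species_map = species_map,
                box = config$box %||% NULL)
  })

  bundle <- list(config = config, stages = stages, outputs = character(0))
  spec <- contact_spec(config$d_on, config$d_off, grouping = config$grouping,
                       resolution = config$resolution)
  sites <- NULL
  if (!is.null(config$sites)) {
    sites <- stats::setNames(
      lapply(config$sites, function(s) as.integer(s$residue_ids)),
      vapply(config$sites, function(s) s$label, ""))
  }

  if ("contacts" %in% stages) {
    ev_all <- list()
    nf_total <- 0L
    dt <- NA_real_
    for (r in seq_along(replicates)) {
      sys <- replicates[[r]]
      ds <- min_distance_series(sys$frames, sys$meta, config$lipid_selection,
                                config$protein_selection,
                                grouping = config$grouping, sites = sites)
      ev <- detect_contacts(ds, spec)
      if (nrow(ev) > 0L) ev$replicate <- r
      ev_all[[r]] <- ev
      nf_total <- nf_total + sys$frames$n_frames
      dt <- ds$dt
    }
    events <- do.call(rbind, ev_all[vapply(ev_all, nrow, 0L) > 0])
    if (is.null(events)) {
      events <- data.frame(lipid = character(0), target = character(0),
                           start_frame = integer(0), end_frame = integer(0),
                           duration_ns = numeric(0), censored = logical(0),
                           replicate = integer(0))
    }
    bundle$events <- events
    bundle$n_frames_total <- nf_total
    bundle$dt <- dt
    bundle$outputs <- c(bundle$outputs,
                        stage_csv(events, config$output_dir, "events"))
  }

  if ("kinetics" %in% stages) {
    fits <- list()
    by_target <- split(bundle$events, bundle$events$target)
    for (tg in names(by_target)) {
      dur <- by_target[[tg]]$duration_ns
      if (length(dur) >= 5L) {
        fit <- fit_koff(survival_curve(dur))
        fits[[tg]] <- fit[c("amplitude_fast", "k_fast", "k_slow", "k_off",
                            "residence_time_ns", "ssr", "n_events", "converged")]
      }
    }
    if (per_replicate) {
      fits_rep <- list()
      for (r in unique(bundle$events$replicate)) {
        evr <- bundle$events[bundle$events$replicate == r, ]
        for (tg in unique(evr$target)) {
          dur <- evr$duration_ns[evr$target == tg]
          if (length(dur) >= 5L) {
            fit <- fit_koff(survival_curve(dur))
            fits_rep[[paste(tg, "rep", r)]] <-
              fit[c("k_off", "residence_time_ns", "n_events", "converged")]
          }
        }
      }
      fits$per_replicate <- fits_rep
    }
    bundle$fits <- fits
    # per-target (residue or site) interaction profile over pooled events
    prof <- residue_profile(bundle$events, bundle$n_frames_total, bundle$dt)
    bundle$profile <- prof
    fit_path <- file.path(config$output_dir, "fits.json")
    jsonlite::write_json(fits, fit_path, auto_unbox = TRUE, digits = NA)
    bundle$outputs <- c(bundle$outputs, fit_path,
                        stage_csv(prof, config$output_dir, "profile"))
  }

  if ("occupancy" %in% stages) {
    lk_assert(!is.null(config$sites), "stage 'occupancy' needs `sites`",
              "lipidkin_validation")
    occ_all <- list()
    for (r in seq_along(replicates)) {
      sys <- replicates[[r]]
      for (s in config$sites) {
        site <- binding_site(s$label, as.integer(s$residue_ids),
                             cutoff = s$cutoff %||% 0.6)
        oc <- site_occupancy(sys$frames, sys$meta, site, config$lipid_selection)
        oc$site <- s$label
        oc$replicate <- r
        occ_all[[length(occ_all) + 1L]] <- oc
      }
    }
    bundle$occupancy <- do.call(rbind, occ_all)
    bundle$outputs <- c(bundle$outputs,
                        stage_csv(bundle$occupancy, config$output_dir, "occupancy"))
  }

  if ("rdf" %in% stages) {
    lk_assert(!is.null(config$rdf), "stage 'rdf' needs an `rdf` config block",
              "lipidkin_validation")
    rdf_all <- list()
    for (r in seq_along(replicates)) {
      sys <- replicates[[r]]
      rp <- lateral_rdf(sys$frames, sys$meta,
                        config$rdf$reference_selection %||% config$protein_selection,
                        config$rdf$species_selection %||% config$lipid_selection,
                        r_max = config$rdf$r_max,
                        n_bins = config$rdf$n_bins %||% 50L,
                        z_range = config$rdf$z_range %||% NULL)
      rp$replicate <- r
      rdf_all[[r]] <- rp
    }
    bundle$rdf <- do.call(rbind, rdf_all)
    bundle$outputs <- c(bundle$outputs,
                        stage_csv(bundle$rdf, config$output_dir, "rdf"))
  }

  if ("angle" %in% stages) {
    lk_assert(!is.null(config$plane), "stage 'angle' needs a `plane` block",
              "lipidkin_validation")
    ps <- plane_spec(as.integer(config$plane$domain1_residues),
                     as.integer(config$plane$domain2_residues),
                     config$plane$particle_rule %||% "backbone_bead")
    ang_all <- list()
    for (r in seq_along(replicates)) {
      sys <- replicates[[r]]
      a <- interdomain_angle(sys$frames, ps, sys$meta)
      sm <- data.frame(a)
      sm$replicate <- r
      attr(sm, "mean") <- attr(a, "mean")
      attr(sm, "sd") <- attr(a, "sd")
      ang_all[[r]] <- sm
    }
    bundle$angle <- ang_all
    bundle$outputs <- c(bundle$outputs,
                        stage_csv(do.call(rbind, ang_all), config$output_dir,
                                  "angle"))
  }

  if ("rmsd" %in% stages) {
    lk_assert(!is.null(config$fit_selection) && !is.null(config$rmsd_selection),
              "stage 'rmsd' needs `fit_selection` and `rmsd_selection`",
              "lipidkin_validation")
    rmsd_all <- list()
    for (r in seq_along(replicates)) {
      sys <- replicates[[r]]
      rd <- domain_rmsd(sys$frames, sys$meta, config$fit_selection,
                        config$rmsd_selection)
      rd$replicate <- r
      rmsd_all[[r]] <- rd
    }
    bundle$rmsd <- do.call(rbind, rmsd_all)
    bundle$outputs <- c(bundle$outputs,
                        stage_csv(bundle$rmsd, config$output_dir, "rmsd"))
  }

  if ("pca" %in% stages) {
    lk_assert(!is.null(config$fit_selection) && !is.null(config$analysis_selection),
              "stage 'pca' needs `fit_selection` and `analysis_selection`",
              "lipidkin_validation")
    pca_all <- list()
    fr1 <- data.frame(replicate = integer(0), fraction_first = numeric(0))
    for (r in seq_along(replicates)) {
      sys <- replicates[[r]]
      pc <- trajectory_pca(sys$frames, sys$meta, config$fit_selection,
                           config$analysis_selection)
      pca_all[[r]] <- pc
      fr1 <- rbind(fr1, data.frame(replicate = r,
                                   fraction_first = pc$fraction_first))
    }
    bundle$pca <- pca_all
    bundle$pca_summary <- fr1
    bundle$outputs <- c(bundle$outputs,
                        stage_csv(fr1, config$output_dir, "pca"))
  }

  manifest <- list(
    package = "lipidkin",
    version = as.character(utils::packageVersion("lipidkin")),
    topology = config$topology,
    trajectories = config$trajectories,
    stages = stages,
    parameters = list(d_on = config$d_on, d_off = config$d_off,
                      grouping = config$grouping,
                      resolution = config$resolution),
    seed = config$seed,
    outputs = basename(bundle$outputs)
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  bundle$manifest <- manifest
  bundle$outputs <- c(bundle$outputs, manifest_path)
  class(bundle) <- "ReportBundle"
  invisible(bundle)
}

#' Human-readable summary of a report bundle
#'
#' Deterministic Markdown mirroring the stage outputs exactly: per-site
#' residence times with event counts, angle mean +/- SD per replicate, and
#' the first-eigenvalue fraction per replicate. Sections whose stage was not
#' run are reported as gaps.
#'
#' @param bundle A `ReportBundle` from [run_pipeline()].
#' @return A character scalar (Markdown).
#' @export
summarize_report <- function(bundle) {
  lk_assert(inherits(bundle, "ReportBundle"), "need a ReportBundle")
  out <- c("# lipidkin run summary", "")
  if (length(bundle$stages) == 0L) {
    return(paste(c(out, "No stages were run."), collapse = "\n"))
  }
  if (!is.null(bundle$profile)) {
    out <- c(out, "## Residence times", "",
             "| target | events | occupancy | residence time (ns) | fitted |",
             "|---|---|---|---|---|",
             sprintf("| %s | %d | %.4f | %.4g | %s |",
                     bundle$profile$target, bundle$profile$n_events,
                     bundle$profile$occupancy,
                     bundle$profile$residence_time_ns,
                     ifelse(bundle$profile$fitted, "yes", "no")), "")
  } else if ("kinetics" %in% bundle$stages) {
    out <- c(out, "## Residence times", "", "_stage ran but produced no fits_", "")
  }
  if (!is.null(bundle$angle)) {
    out <- c(out, "## ECD-TMD style inter-domain angle", "",
             "| replicate | mean (deg) | sd (deg) |", "|---|---|---|",
             vapply(seq_along(bundle$angle), function(r) {
               sprintf("| %d | %.2f | %.2f |", r,
                       attr(bundle$angle[[r]], "mean"),
                       attr(bundle$angle[[r]], "sd"))
             }, ""), "")
  }
  if (!is.null(bundle$pca_summary)) {
    out <- c(out, "## PCA: first-eigenvalue fraction", "",
             "| replicate | fraction |", "|---|---|",
             sprintf("| %d | %.4f |", bundle$pca_summary$replicate,
                     bundle$pca_summary$fraction_first), "")
  }
  missing <- setdiff(c("kinetics", "angle", "pca"), bundle$stages)
  if (length(missing) > 0L) {
    out <- c(out, sprintf("_Not run: %s._", paste(missing, collapse = ", ")))
  }
  paste(out, collapse = "\n")
}
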