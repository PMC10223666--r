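# Batch driver: validate a run configuration, execute every analyzer over a
# trajectory, and emit per-analysis CSV artifacts plus a one-row summary and
# a manifest sufficient to re-run the analysis exactly.

config_defaults <- function() {
  list(
    label = "run",
    seed = 1L,
    output_dir = "vesitraj-output",
    input = list(
      trajectory = NULL, format = "xyz", timestep_ns = 0.01, topology = NULL
    ),
    equilibration_fraction = 0.1,
    geometry = list(
      contact_cutoff_A = 6, dead_zone_cos = 0.2, radius_convention = "outer",
      run_aggregates = FALSE
    ),
    dynamics = list(
      max_lag_ns = NULL, fit_dimension = 3L, fit_window_fraction = c(0.1, 0.5),
      anomalous_threshold = 0.2, min_dwell_frames = 20L
    ),
    surface = list(
      probe_radius_A = 1.4, n_sphere_points = 960L,
      sasa_selection = "amphiphile", sasa_stride = 10L,
      run_sasa = TRUE, run_order = TRUE, run_density = TRUE,
      density_leaflet = "outer", density_n_cos = 12L, density_n_phi = 24L,
      rdf_r_max_A = 30, rdf_bin_width_A = 0.5
    ),
    peptide = list(cutoff_A = 8, min_support = 5L)
  )
}

# merge user values over defaults; unknown keys and range violations are
# collected (all at once) rather than failing on the first
merge_config <- function(defaults, user, path, errors) {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) {
      errors$msgs <- c(errors$msgs, sprintf("unknown key: %s", full))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        errors$msgs <- c(errors$msgs, sprintf("%s must be a block", full))
      } else {
        defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full, errors)
      }
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

check_positive <- function(cfg, keys, errors) {
  for (k in keys) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    v <- cfg
    for (p in parts) v <- v[[p]]
    if (!is.null(v) && (!is.numeric(v) || any(v <= 0))) {
      errors$msgs <- c(errors$msgs, sprintf("%s must be positive (got %s)", k,
        paste(v, collapse = ", ")))
    }
  }
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills defaults, and enforces a strict schema:
#' every unknown key is an error (no silent typos), and all schema
#' violations are reported together.
#'
#' @param path YAML configuration path, or a named list.
#' @return the fully resolved configuration (list of class `run_config`);
#'   aborts with the aggregated error list otherwise.
#' @export
validate_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file not found: %s", path), class = "vesitraj_io_error")
    }
    yaml::read_yaml(path)
  } else {
    path
  }
  errors <- new.env()
  errors$msgs <- character(0)
  cfg <- merge_config(config_defaults(), user %||% list(), "", errors)
  check_positive(cfg, c(
    "input.timestep_ns", "geometry.contact_cutoff_A",
    "surface.probe_radius_A", "surface.n_sphere_points",
    "surface.sasa_stride", "surface.rdf_r_max_A", "surface.rdf_bin_width_A",
    "peptide.cutoff_A", "peptide.min_support", "dynamics.min_dwell_frames"
  ), errors)
  if (!is.null(cfg$input$trajectory) && !file.exists(cfg$input$trajectory)) {
    errors$msgs <- c(errors$msgs,
      sprintf("input.trajectory does not exist: %s", cfg$input$trajectory))
  }
  if (!is.null(cfg$input$topology) && !file.exists(cfg$input$topology)) {
    errors$msgs <- c(errors$msgs,
      sprintf("input.topology does not exist: %s", cfg$input$topology))
  }
  if (!cfg$input$format %in% c("pdb", "xyz")) {
    errors$msgs <- c(errors$msgs,
      sprintf("input.format must be 'pdb' or 'xyz' (got %s)", cfg$input$format))
  }
  if (cfg$geometry$dead_zone_cos < 0 || cfg$geometry$dead_zone_cos >= 1) {
    errors$msgs <- c(errors$msgs, "geometry.dead_zone_cos must be in [0, 1)")
  }
  if (cfg$equilibration_fraction < 0 || cfg$equilibration_fraction >= 1) {
    errors$msgs <- c(errors$msgs, "equilibration_fraction must be in [0, 1)")
  }
  if (length(errors$msgs) > 0) {
    abort(paste0("invalid configuration:\n",
      paste0("  - ", errors$msgs, collapse = "\n")),
      class = "vesitraj_config_error")
  }
  structure(cfg, class = "run_config")
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

write_artifact <- function(df, dir, name) {
  path <- file.path(dir, name)
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: trajectory read, leaflet assignment and per-frame
#' geometry, MSD/diffusion, flip-flop detection, SASA, order parameters,
#' density map, and (when a peptide is present) the peptide-headgroup RDF
#' and tilt series. Per-frame values are time-averaged over the equilibrated
#' window (the first `equilibration_fraction` of frames is discarded). All
#' artifacts are CSV with fixed formatting; a manifest records the resolved
#' configuration, its hash and the seed, so identical config + input + seed
#' give byte-identical outputs.
#'
#' @param config a `run_config` from [validate_config()], or a path/list
#'   accepted by it.
#' @param system optional in-memory `vesicle_system`; when given,
#'   `input.trajectory`/`input.topology` are not read.
#' @return one-row summary tibble (`label`, `radius_nm`, `thickness_nm`,
#'   `inner_leaflet_pct`, `diffusion_nm2_ns`, `anomalous`, `alpha_hat`,
#'   `sasa_nm2`, `flipflop_count`, `n_frames_analyzed`), with the artifact
#'   paths in attribute `"artifacts"`.
#' @export
run_pipeline <- function(config, system = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  set.seed(config$seed)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  failed_marker <- file.path(config$output_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
        failed_marker)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "vesitraj_stage_error", parent = e)
    })
    message(sprintf("[vesitraj] stage %-10s %6.2f s", name,
      proc.time()[["elapsed"]] - t0))
    res
  }

  loaded <- stage("input", {
    if (!is.null(system)) {
      list(traj = system$trajectory, map = system$map)
    } else {
      if (is.null(config$input$trajectory) || is.null(config$input$topology)) {
        abort("config must name input.trajectory and input.topology")
      }
      traj <- read_trajectory(config$input$trajectory, config$input$format,
        timestep = config$input$timestep_ns)
      map <- build_molecule_map(traj, read_topology_spec(config$input$topology))
      list(traj = traj, map = map)
    }
  })
  traj <- loaded$traj
  map <- loaded$map
  nf <- n_frames(traj)
  equil <- max(1L, floor(config$equilibration_fraction * nf) + 1L)
  frames_an <- equil:nf
  has_peptide <- length(select_atoms(map, species = "peptide")) > 0

  geom <- stage("geometry", {
    g <- geometry_series(traj, map, frames = frames_an,
      dead_zone = config$geometry$dead_zone_cos,
      radius_convention = config$geometry$radius_convention)
    artifacts <<- c(artifacts, write_artifact(g, config$output_dir, "geometry_per_frame.csv"))
    if (config$geometry$run_aggregates) {
      agg <- detect_aggregates(frame_coords(traj, nf), map,
        contact_cutoff = config$geometry$contact_cutoff_A)
      artifacts <<- c(artifacts,
        write_artifact(agg$members, config$output_dir, "aggregates_last_frame.csv"))
    }
    g
  })

  dyn <- stage("dynamics", {
    if (nf >= 10) {
      mc <- msd(traj, map, max_lag = config$dynamics$max_lag_ns)
      fit <- tryCatch(
        diffusion_coefficient(mc, e_dim = config$dynamics$fit_dimension,
          fit_window = config$dynamics$fit_window_fraction * max(mc$lag_ns),
          anomalous_threshold = config$dynamics$anomalous_threshold),
        vesitraj_fit_error = function(e) NULL
      )
      artifacts <<- c(artifacts, write_artifact(mc, config$output_dir, "msd.csv"))
      if (!is.null(fit)) {
        artifacts <<- c(artifacts,
          write_artifact(glance(fit), config$output_dir, "diffusion.csv"))
      }
      lab_ts <- leaflet_timeseries(traj, map,
        dead_zone = config$geometry$dead_zone_cos)
      ff <- detect_flip_flops(lab_ts, min_dwell = config$dynamics$min_dwell_frames)
      ev <- ff$events
      ev$t_start_ns <- (ev$frame_start - 1) * traj$timestep
      ev$t_end_ns <- (ev$frame_end - 1) * traj$timestep
      artifacts <<- c(artifacts, write_artifact(ev, config$output_dir, "flipflops.csv"))
      list(fit = fit, flips = ff)
    } else {
      list(fit = NULL, flips = NULL)
    }
  })

  surf <- stage("surface", {
    out <- list(sasa_mean = NA_real_)
    labels_last <- assign_leaflets(frame_coords(traj, nf), map,
      dead_zone = config$geometry$dead_zone_cos)
    if (config$surface$run_sasa) {
      sasa_frames <- frames_an[seq(1, length(frames_an),
        by = config$surface$sasa_stride)]
      radii <- default_radius_table(config$surface$probe_radius_A)
      sel <- select_atoms(map, species = config$surface$sasa_selection)
      vals <- vapply(sasa_frames, function(f) {
        sasa(frame_coords(traj, f), map, radii = radii,
          n_points = config$surface$n_sphere_points, selection = sel)$total_nm2
      }, numeric(1))
      artifacts <<- c(artifacts, write_artifact(
        tibble::tibble(frame = sasa_frames, sasa_nm2 = vals),
        config$output_dir, "sasa.csv"))
      out$sasa_mean <- mean(vals)
    }
    if (config$surface$run_order) {
      op <- order_parameters(traj, map, frames = frames_an)
      artifacts <<- c(artifacts, write_artifact(op, config$output_dir, "order.csv"))
    }
    if (config$surface$run_density) {
      dm <- density_map(traj, map, labels_last,
        leaflet = config$surface$density_leaflet,
        n_cos = config$surface$density_n_cos,
        n_phi = config$surface$density_n_phi, frames = frames_an)
      artifacts <<- c(artifacts, write_artifact(dm, config$output_dir, "density_map.csv"))
    }
    if (has_peptide) {
      idxs <- amphiphile_index(map)
      heads <- c(idxs$o1, idxs$o2)
      rc <- rdf(traj, map,
        group_a = select_atoms(map, species = "peptide"),
        group_b = heads,
        r_max = config$surface$rdf_r_max_A,
        bin_width = config$surface$rdf_bin_width_A, frames = frames_an)
      artifacts <<- c(artifacts, write_artifact(rc, config$output_dir, "rdf.csv"))
    }
    out
  })

  tilt_mean <- NA_real_
  if (has_peptide) {
    stage("peptide", {
      ts <- tilt_series(traj, map, cutoff = config$peptide$cutoff_A,
        min_support = config$peptide$min_support, frames = frames_an)
      artifacts <<- c(artifacts, write_artifact(ts, config$output_dir, "tilt.csv"))
      tilt_mean <<- mean(ts$tilt_deg, na.rm = TRUE)
      NULL
    })
  }

  summary <- stage("summary", {
    fit <- dyn$fit
    srow <- tibble::tibble(
      label = config$label,
      radius_nm = round(mean(geom$radius_nm), 2),
      thickness_nm = round(mean(geom$thickness_nm), 2),
      inner_leaflet_pct = round(mean(geom$inner_fraction_pct), 1),
      diffusion_nm2_ns = if (is.null(fit) || fit$anomalous) NA_real_ else round(fit$d, 2),
      anomalous = if (is.null(fit)) NA else fit$anomalous,
      alpha_hat = if (is.null(fit)) NA_real_ else round(fit$alpha_hat, 3),
      sasa_nm2 = if (is.na(surf$sasa_mean)) NA_real_ else round(surf$sasa_mean),
      flipflop_count = if (is.null(dyn$flips)) NA_integer_ else dyn$flips$count,
      tilt_mean_deg = if (is.na(tilt_mean)) NA_real_ else round(tilt_mean, 1),
      n_frames_analyzed = length(frames_an)
    )
    artifacts <<- c(artifacts, write_artifact(srow, config$output_dir, "summary.csv"))
    srow
  })

  manifest <- list(
    package = "vesitraj",
    version = as.character(utils::packageVersion("vesitraj")),
    label = config$label,
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    artifacts = basename(artifacts)
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(summary, "artifacts") <- c(artifacts, file.path(config$output_dir, "manifest.json"))
  summary
}

#' Merge summary rows across runs
#'
#' @param paths character vector of `summary.csv` paths (or run output
#'   directories).
#' @return tibble with one row per run.
#' @export
merge_summaries <- function(paths) {
  paths <- ifelse(dir.exists(paths), file.path(paths, "summary.csv"), paths)
  dplyr::bind_rows(lapply(paths, function(p) {
    tibble::as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
  }))
}
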