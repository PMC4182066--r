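#' Run configuration
#'
#' Bundles everything one reproduction run needs: geometry (generator
#' parameters or a mesh file path), material, load overrides, time
#' integration and analysis settings, and the output directory.
#'
#' @param geometry an \code{\link{orbit_params}} object or a mesh file
#'   path (\code{.msh}/\code{.vtk}).
#' @param material a \code{\link{material}}.
#' @param load list of overrides for the default strike:
#'   \code{peak_force_per_node} (N), \code{direction} (length-3),
#'   \code{force_scale} (multiplier), \code{profile_knots}.
#' @param integration a \code{\link{time_config}}.
#' @param analysis list with \code{axis_mode}, \code{epsilon} (mm),
#'   \code{stress_limit} (MPa).
#' @param output_dir where \code{\link{run_reproduction}} writes results.
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(geometry = orbit_params(), material = NULL,
                       load = list(), integration = time_config(),
                       analysis = list(
                         axis_mode = "wall_normal", epsilon = 0.1,
                         stress_limit = 80
                       ),
                       output_dir = "orbishock_run", log_level = "info") {
  if (is.null(material)) material <- orbital_bone_material()
  stopifnot(
    inherits(geometry, "orbit_params") || is.character(geometry),
    inherits(material, "material"),
    inherits(integration, "time_config"),
    is.list(load), is.list(analysis)
  )
  analysis <- utils::modifyList(
    list(axis_mode = "wall_normal", epsilon = 0.1, stress_limit = 80),
    analysis
  )
  stopifnot(
    analysis$axis_mode %in% c("wall_normal", "orbital_axis"),
    analysis$epsilon > 0, analysis$stress_limit > 0
  )
  structure(
    list(
      geometry = geometry, material = material, load = load,
      integration = integration, analysis = analysis,
      output_dir = output_dir, log_level = log_level
    ),
    class = "run_config"
  )
}

#' Read and write run configurations as YAML
#'
#' The YAML layout mirrors the \code{\link{run_config}} blocks; a file
#' without a \code{material} block is rejected before any computation.
#'
#' @param path YAML file.
#' @param config a \code{run_config}.
#' @return \code{read_run_config} returns a \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$material)) {
    stop("run config lacks the required 'material' block", call. = FALSE)
  }
  geometry <- if (is.character(raw$geometry)) {
    raw$geometry
  } else {
    do.call(orbit_params, raw$geometry %||% list())
  }
  integ <- do.call(time_config, raw$integration %||% list())
  run_config(
    geometry = geometry,
    material = do.call(material, raw$material),
    load = raw$load %||% list(),
    integration = integ,
    analysis = raw$analysis %||% list(),
    output_dir = raw$output_dir %||% "orbishock_run",
    log_level = raw$log_level %||% "info"
  )
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  mat <- config$material
  out <- list(
    geometry = if (is.character(config$geometry)) {
      config$geometry
    } else {
      unclass(config$geometry)
    },
    material = list(
      youngs_modulus = mat$youngs_modulus,
      poisson_ratio = mat$poisson_ratio,
      density = mat$density,
      rayleigh_alpha = mat$rayleigh_alpha,
      rayleigh_beta = mat$rayleigh_beta
    ),
    load = config$load,
    integration = unclass(config$integration),
    analysis = config$analysis,
    output_dir = config$output_dir,
    log_level = config$log_level
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

resolve_strike <- function(mesh, load) {
  case <- default_strike_load(
    mesh,
    peak_force_per_node = load$peak_force_per_node %||% 2400,
    direction = unlist(load$direction %||% c(1, 0, 0))
  )
  if (!is.null(load$profile_knots)) {
    case <- load_case(
      case$load_nodes, case$direction, case$peak_force_per_node,
      load$profile_knots
    )
  }
  if (!is.null(load$force_scale)) {
    case$peak_force_per_node <- case$peak_force_per_node * load$force_scale
  }
  case
}

# reference observations from the original CT-derived orbital model; kept
# in the report for side-by-side display only -- the synthetic geometry is
# not expected to reproduce them quantitatively
reference_observations <- function() {
  list(
    note = paste(
      "Displacement magnitudes observed on the original CT-derived orbital",
      "model; non-binding for the synthetic average-orbit geometry."
    ),
    floor_displacement_at_1ms_mm = 1.0,
    peak_outward_mm = c(4.0, 4.5),
    peak_inward_mm = 2.0,
    outward_peak_time_s = c(4e-3, 5e-3),
    inward_peak_time_s = c(8e-3, 9e-3),
    probe_A_outward_mm = 4.37,
    probe_A_inward_mm = 1.55,
    probe_A_peak_to_peak_mm = 5.92,
    stress_exceedance_time_s = 2.6e-3
  )
}

#' Execute the full reproduction pipeline
#'
#' Generates (or loads) the geometry, assembles the shell system, applies
#' the strike load, integrates the 10 ms transient, analyzes the
#' displacement wave, and writes the result set into
#' \code{config$output_dir}: the serialized config, the mesh, a VTK
#' snapshot series with displacement/velocity point data and von Mises
#' element data, probe and energy CSV traces, the per-region extrema CSV,
#' the JSON wave report (with non-binding reference observations), and a
#' JSON run manifest.
#'
#' @param config a \code{\link{run_config}}.
#' @return the manifest, invisibly, as an object of class
#'   \code{run_manifest}.
#' @export
run_reproduction <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t_all <- Sys.time()
  say <- function(...) {
    if (!identical(config$log_level, "quiet")) message(...)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
    list(result = out, seconds = as.numeric(Sys.time() - t0, units = "secs"))
  }

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  say("stage: geometry")
  geo <- stage("geometry", {
    if (is.character(config$geometry)) {
      read_mesh(config$geometry)
    } else {
      generate_orbit(config$geometry)
    }
  })
  mesh <- geo$result

  say("stage: assembly")
  asm <- stage("assembly", assemble(mesh, config$material))
  system <- asm$result

  say("stage: load + integration")
  dyn <- stage("integration", {
    case <- resolve_strike(mesh, config$load)
    list(case = case, history = integrate_transient(
      system, case, config$integration
    ))
  })
  history <- dyn$result$history

  say("stage: analysis")
  ana <- stage("analysis", {
    report <- wave_report(
      history, mesh, config$material,
      axis_mode = config$analysis$axis_mode,
      epsilon = config$analysis$epsilon,
      stress_limit = config$analysis$stress_limit
    )
    stress <- recover_stress(history, mesh, config$material)
    list(report = report, stress = stress)
  })
  report <- ana$result$report
  stress <- ana$result$stress

  say("stage: outputs")
  outp <- stage("outputs", {
    od <- config$output_dir
    files <- character()
    cfg_path <- file.path(od, "config.yaml")
    write_run_config(config, cfg_path)
    files <- c(files, cfg_path)
    mesh_path <- file.path(od, "mesh.vtk")
    write_mesh(mesh, mesh_path)
    files <- c(files, mesh_path)
    files <- c(files, write_vtk_series(mesh, history, stress, od))
    field <- signed_wall_displacement(
      history, mesh, config$analysis$axis_mode
    )
    probe_path <- file.path(od, "probe_A.csv")
    pA <- mesh$probe_A
    utils::write.csv(
      data.frame(
        time_s = history$times,
        ux_mm = history$U[6L * (pA - 1L) + 1L, ],
        uy_mm = history$U[6L * (pA - 1L) + 2L, ],
        uz_mm = history$U[6L * (pA - 1L) + 3L, ],
        signed_mm = field$s[pA, ]
      ),
      probe_path, row.names = FALSE
    )
    files <- c(files, probe_path)
    energy_path <- file.path(od, "energy.csv")
    utils::write.csv(history$energy, energy_path, row.names = FALSE)
    files <- c(files, energy_path)
    region_path <- file.path(od, "per_region.csv")
    utils::write.csv(report$per_region, region_path, row.names = FALSE)
    files <- c(files, region_path)
    report_path <- file.path(od, "report.json")
    rep_json <- unclass(report)
    rep_json$per_region <- NULL
    rep_json$reference_observations <- reference_observations()
    jsonlite::write_json(
      rep_json, report_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
    files <- c(files, report_path)
    files
  })

  manifest <- structure(
    list(
      package_version = as.character(tryCatch(
        utils::packageVersion("orbishock"),
        error = function(e) "dev"
      )),
      config_md5 = unname(tools::md5sum(file.path(
        config$output_dir, "config.yaml"
      ))),
      stage_seconds = list(
        geometry = geo$seconds, assembly = asm$seconds,
        integration = dyn$seconds, analysis = ana$seconds,
        outputs = outp$seconds,
        total = as.numeric(Sys.time() - t_all, units = "secs")
      ),
      files = basename(outp$result),
      report = list(
        peak_outward_mm = report$peak_outward$mm,
        peak_inward_mm = report$peak_inward$mm,
        reversal_onset_s = report$reversal_onset,
        probe_A_peak_to_peak_mm = report$probe_A_peak_to_peak,
        stress_first_exceedance_s = report$stress_first_exceedance
      )
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(
    unclass(manifest), file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  say(sprintf(
    "run complete: %s (%.1f s)", config$output_dir,
    manifest$stage_seconds$total
  ))
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest (orbishock ", x$package_version, ")\n", sep = "")
  cat("  files:", paste(x$files, collapse = ", "), "\n")
  cat(sprintf("  total wall time: %.1f s\n", x$stage_seconds$total))
  cat(sprintf(
    "  peaks: outward %.3f mm / inward %.3f mm; reversal %s s\n",
    x$report$peak_outward_mm, x$report$peak_inward_mm,
    format(x$report$reversal_onset_s)
  ))
  invisible(x)
}

# one legacy-VTK file per snapshot plus a ParaView .series index
write_vtk_series <- function(mesh, history, stress, dir) {
  files <- character()
  nnode <- nrow(mesh$nodes)
  for (k in seq_along(history$times)) {
    fname <- sprintf("snapshot_%03d.vtk", k - 1L)
    fpath <- file.path(dir, fname)
    con <- file(fpath, "w")
    wl <- function(...) writeLines(paste0(...), con)
    wl("# vtk DataFile Version 3.0")
    wl(sprintf("orbishock snapshot t=%g s", history$times[k]))
    wl("ASCII")
    wl("DATASET UNSTRUCTURED_GRID")
    wl("POINTS ", nnode, " double")
    writeLines(apply(mesh$nodes, 1L, function(r) {
      paste(fmt_num(r), collapse = " ")
    }), con)
    m <- nrow(mesh$triangles)
    wl("CELLS ", m, " ", 4L * m)
    writeLines(apply(mesh$triangles - 1L, 1L, function(r) {
      paste(c(3L, r), collapse = " ")
    }), con)
    wl("CELL_TYPES ", m)
    writeLines(rep("5", m), con)
    wl("POINT_DATA ", nnode)
    for (what in c("displacement", "velocity")) {
      src <- if (what == "displacement") history$U else history$V
      wl("VECTORS ", what, " double")
      writeLines(vapply(seq_len(nnode), function(nd) {
        paste(fmt_num(src[6L * (nd - 1L) + 1:3, k]), collapse = " ")
      }, character(1)), con)
    }
    wl("CELL_DATA ", m)
    wl("SCALARS von_mises_top double 1")
    wl("LOOKUP_TABLE default")
    writeLines(fmt_num(stress$von_mises_top[, k]), con)
    wl("SCALARS von_mises_bottom double 1")
    wl("LOOKUP_TABLE default")
    writeLines(fmt_num(stress$von_mises_bottom[, k]), con)
    close(con)
    files <- c(files, fpath)
  }
  idx <- file.path(dir, "snapshots.vtk.series")
  jsonlite::write_json(
    list(
      `file-series-version` = "1.0",
      files = lapply(seq_along(history$times), function(k) {
        list(name = basename(files[k]), time = history$times[k])
      })
    ),
    idx,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  c(files, idx)
}
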