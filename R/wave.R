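#' Region label of each node
#'
#' A node inherits the region of the majority of its incident elements
#' (ties broken by fixed label order), matching how wall-wise motion is
#' read off node displacement fields.
#'
#' @param mesh a \code{\link{shell_mesh}}.
#' @return character vector, one label per node.
#' @keywords internal
node_regions <- function(mesh) {
  levs <- unique(mesh$region)
  counts <- matrix(0L, nrow(mesh$nodes), length(levs))
  colnames(counts) <- levs
  for (k in 1:3) {
    idx <- cbind(mesh$triangles[, k], match(mesh$region, levs))
    for (r in seq_len(nrow(idx))) {
      counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1L
    }
  }
  levs[max.col(counts, ties.method = "first")]
}

#' Signed wall displacement field
#'
#' Projects the nodal translation history on a per-node axis with the sign
#' convention positive = toward the orbital interior, negative = toward
#' the sinuses/exterior.  \code{wall_normal} (default) projects on the
#' area-weighted node normal (which points into the cavity);
#' \code{orbital_axis} takes the x (orbital-axis) displacement component
#' signed by the wall side, i.e. by the sign of the node normal's x
#' component.
#'
#' @param history a \code{displacement_history}.
#' @param mesh the \code{\link{shell_mesh}} the history was computed on.
#' @param axis_mode \code{"wall_normal"} or \code{"orbital_axis"}.
#' @return object of class \code{signed_displacement_field}: list with
#'   \code{times}, \code{s} (n_nodes x n_snapshots, mm), \code{axis_mode},
#'   \code{node_region}, \code{fixed_nodes}, \code{probe_A}.
#' @export
signed_wall_displacement <- function(history, mesh,
                                     axis_mode = c(
                                       "wall_normal", "orbital_axis"
                                     )) {
  axis_mode <- match.arg(axis_mode)
  nnode <- nrow(mesh$nodes)
  if (nrow(history$U) != 6L * nnode) {
    stop("history and mesh node counts disagree", call. = FALSE)
  }
  nn <- mesh_node_normals(mesh)
  ux <- history$U[seq(1L, by = 6L, length.out = nnode), , drop = FALSE]
  uy <- history$U[seq(2L, by = 6L, length.out = nnode), , drop = FALSE]
  uz <- history$U[seq(3L, by = 6L, length.out = nnode), , drop = FALSE]
  s <- if (axis_mode == "wall_normal") {
    nn[, 1L] * ux + nn[, 2L] * uy + nn[, 3L] * uz
  } else {
    sign(nn[, 1L]) * ux
  }
  structure(
    list(
      times = history$times, s = s, axis_mode = axis_mode,
      node_region = node_regions(mesh), fixed_nodes = mesh$fixed_nodes,
      probe_A = mesh$probe_A
    ),
    class = "signed_displacement_field"
  )
}

#' Detect the retrograde (recurring) wave
#'
#' Finds the earliest snapshot at which any node of the floor or medial
#' wall crosses from beyond \code{-epsilon} (outward, toward the sinus) to
#' beyond \code{+epsilon} (inward, toward the orbit) -- the onset of the
#' late-phase reversal.
#'
#' @param field a \code{\link{signed_wall_displacement}} result.
#' @param epsilon detection threshold (mm); must exceed numerical noise
#'   and stay below the smallest physical relocation of interest.
#' @param regions regions scanned for the reversal.
#' @return list with \code{onset} (time s, or \code{NA} if no reversal),
#'   \code{snapshot} (index), \code{nodes} (reversing at onset) and
#'   \code{regions} (their labels).
#' @export
detect_retrograde <- function(field, epsilon = 0.1,
                              regions = c(
                                "floor_anterior", "floor_posterior", "medial"
                              )) {
  stopifnot(epsilon > 0)
  sel <- which(field$node_region %in% regions)
  s <- field$s[sel, , drop = FALSE]
  nsnap <- ncol(s)
  onset_idx <- rep(NA_integer_, length(sel))
  for (i in seq_along(sel)) {
    been_out <- FALSE
    for (k in seq_len(nsnap)) {
      if (s[i, k] < -epsilon) been_out <- TRUE
      if (been_out && s[i, k] > epsilon) {
        onset_idx[i] <- k
        break
      }
    }
  }
  if (all(is.na(onset_idx))) {
    return(list(
      onset = NA_real_, snapshot = NA_integer_,
      nodes = integer(), regions = character()
    ))
  }
  k0 <- min(onset_idx, na.rm = TRUE)
  hit <- sel[!is.na(onset_idx) & onset_idx == k0]
  list(
    onset = field$times[k0], snapshot = k0, nodes = hit,
    regions = sort(unique(field$node_region[hit]))
  )
}

#' Outward/inward displacement metrics at a probe node
#'
#' @param field a \code{\link{signed_wall_displacement}} result.
#' @param probe node index; defaults to the probe recorded in the field.
#' @return list with \code{outward} (mm, max of -field), \code{inward}
#'   (mm, max of +field), \code{peak_to_peak} (their sum),
#'   \code{outward_time}, \code{inward_time} (s).
#' @export
probe_metrics <- function(field, probe = field$probe_A) {
  if (is.na(probe)) stop("no probe node available", call. = FALSE)
  if (probe %in% field$fixed_nodes) {
    stop("probe node is fixed", call. = FALSE)
  }
  tr <- field$s[probe, ]
  outward <- max(0, max(-tr))
  inward <- max(0, max(tr))
  list(
    outward = outward,
    inward = inward,
    peak_to_peak = outward + inward,
    outward_time = field$times[which.max(-tr)],
    inward_time = field$times[which.max(tr)]
  )
}

#' Full wave report of a run
#'
#' Collects the quantities characterizing the outward-then-retrograde
#' displacement wave: global outward/inward extrema with time and region,
#' reversal onset, probe-node metrics, per-region extrema, and the first
#' stress-limit exceedance in the floor.
#'
#' @param history a \code{displacement_history}.
#' @param mesh the mesh of the run.
#' @param material the material of the run (for stress recovery).
#' @param axis_mode projection mode, see
#'   \code{\link{signed_wall_displacement}}.
#' @param epsilon reversal threshold (mm).
#' @param stress_limit von Mises fracture-surrogate limit (MPa).
#' @return object of class \code{wave_report}.
#' @export
wave_report <- function(history, mesh, material,
                        axis_mode = "wall_normal", epsilon = 0.1,
                        stress_limit = 80) {
  field <- signed_wall_displacement(history, mesh, axis_mode)
  s <- field$s
  io <- which(s == min(s), arr.ind = TRUE)[1L, ]
  ii <- which(s == max(s), arr.ind = TRUE)[1L, ]
  retro <- detect_retrograde(field, epsilon)
  probe <- probe_metrics(field)
  regions <- sort(unique(field$node_region))
  per_region <- data.frame(
    region = regions,
    peak_outward_mm = vapply(regions, function(r) {
      max(0, max(-s[field$node_region == r, , drop = FALSE]))
    }, numeric(1)),
    peak_inward_mm = vapply(regions, function(r) {
      max(0, max(s[field$node_region == r, , drop = FALSE]))
    }, numeric(1)),
    row.names = NULL
  )
  stress <- recover_stress(history, mesh, material)
  exc <- first_exceedance(stress, stress_limit, mesh)
  structure(
    list(
      axis_mode = axis_mode,
      epsilon_mm = epsilon,
      stress_limit_mpa = stress_limit,
      peak_outward = list(
        mm = max(0, -min(s)), time = field$times[io[2L]],
        region = field$node_region[io[1L]]
      ),
      peak_inward = list(
        mm = max(0, max(s)), time = field$times[ii[2L]],
        region = field$node_region[ii[1L]]
      ),
      reversal_onset = retro$onset,
      reversal_regions = retro$regions,
      probe_A_outward = probe$outward,
      probe_A_inward = probe$inward,
      probe_A_peak_to_peak = probe$peak_to_peak,
      probe_A_outward_time = probe$outward_time,
      probe_A_inward_time = probe$inward_time,
      stress_first_exceedance = exc$time,
      stress_exceedance_element = exc$element,
      stress_exceedance_region = exc$region,
      per_region = per_region
    ),
    class = "wave_report"
  )
}

#' @export
print.wave_report <- function(x, ...) {
  cat("Wave report (", x$axis_mode, " projection)\n", sep = "")
  cat(sprintf(
    "  peak outward: %.3f mm at t = %g s (%s)\n",
    x$peak_outward$mm, x$peak_outward$time, x$peak_outward$region
  ))
  cat(sprintf(
    "  peak inward : %.3f mm at t = %g s (%s)\n",
    x$peak_inward$mm, x$peak_inward$time, x$peak_inward$region
  ))
  cat(sprintf(
    "  retrograde reversal onset: %s\n",
    ifelse(is.na(x$reversal_onset), "none",
      sprintf("%g s (%s)", x$reversal_onset,
        paste(x$reversal_regions, collapse = ", "))
    )
  ))
  cat(sprintf(
    "  probe A: outward %.3f mm, inward %.3f mm, peak-to-peak %.3f mm\n",
    x$probe_A_outward, x$probe_A_inward, x$probe_A_peak_to_peak
  ))
  cat(sprintf(
    "  first stress exceedance (> %g MPa): %s\n",
    x$stress_limit_mpa,
    ifelse(is.na(x$stress_first_exceedance), "none",
      sprintf("%g s (element %d, %s)", x$stress_first_exceedance,
        x$stress_exceedance_element, x$stress_exceedance_region))
  ))
  invisible(x)
}
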