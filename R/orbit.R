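#' Parameters of the synthetic average-orbit mesh
#'
#' The generator emulates a left adult orbit as a frustum-like shell: four
#' walls converge from a rounded-rectangular anterior rim to a truncated
#' posterior apex carrying the optic-canal aperture, with an
#' inferior-orbital-fissure slit separating the posterior floor from the
#' lateral wall.  Defaults are standard adult anatomical averages; wall
#' thicknesses encode that the floor is thicker posteriorly than
#' anteriorly.
#'
#' Coordinate convention: origin at the rim centroid, +x posterior along
#' the orbital axis, +y medial, +z superior (left orbit).
#'
#' @param rim_width medial-lateral extent of the orbital entrance (mm).
#' @param rim_height superior-inferior extent of the entrance (mm).
#' @param depth rim plane to apex along the orbital axis (mm).
#' @param thickness_map named list of wall thickness (mm) for
#'   \code{floor_anterior}, \code{floor_posterior}, \code{medial},
#'   \code{roof}, \code{lateral} and \code{rim_band}.
#' @param optic_canal_radius radius of the apex aperture (mm).
#' @param fissure_length,fissure_width inferior-orbital-fissure slit size
#'   (mm); width 0 suppresses the slit.
#' @param target_elements requested triangle count; the generated count is
#'   within 10 percent.
#' @param seed integer seed for the node jitter.
#' @param jitter node jitter amplitude as a fraction of the local edge
#'   length (0 disables; at most 0.05 is sensible).
#' @return object of class \code{orbit_params}.
#' @export
orbit_params <- function(rim_width = 40, rim_height = 35, depth = 45,
                         thickness_map = list(
                           floor_anterior = 0.5, floor_posterior = 1.0,
                           medial = 0.3, roof = 1.0, lateral = 1.5,
                           rim_band = 3.0
                         ),
                         optic_canal_radius = 2.5,
                         fissure_length = 20, fissure_width = 3,
                         target_elements = 969, seed = 1L, jitter = 0.05) {
  req <- c(
    "floor_anterior", "floor_posterior", "medial", "roof", "lateral",
    "rim_band"
  )
  if (!all(req %in% names(thickness_map))) {
    stop(
      "thickness_map must name: ", paste(req, collapse = ", "),
      call. = FALSE
    )
  }
  th <- unlist(thickness_map[req])
  stopifnot(
    rim_width > 0, rim_height > 0, depth > 0,
    optic_canal_radius > 0,
    fissure_length >= 0, fissure_width >= 0,
    target_elements >= 100,
    all(th > 0.05), all(th < 5.0),
    jitter >= 0, jitter <= 0.2
  )
  if (optic_canal_radius >= min(rim_width, rim_height) / 2) {
    stop(
      "infeasible aperture: optic_canal_radius must be smaller than the ",
      "rim half-axes",
      call. = FALSE
    )
  }
  structure(
    list(
      rim_width = rim_width, rim_height = rim_height, depth = depth,
      thickness_map = as.list(th), optic_canal_radius = optic_canal_radius,
      fissure_length = fissure_length, fissure_width = fissure_width,
      target_elements = as.integer(target_elements), seed = as.integer(seed),
      jitter = jitter
    ),
    class = "orbit_params"
  )
}

#' @export
print.orbit_params <- function(x, ...) {
  cat("Orbit generator parameters\n")
  cat(sprintf(
    "  rim %g x %g mm, depth %g mm, canal radius %g mm\n",
    x$rim_width, x$rim_height, x$depth, x$optic_canal_radius
  ))
  cat(sprintf(
    "  fissure %g x %g mm, target %d elements, seed %d, jitter %g\n",
    x$fissure_length, x$fissure_width, x$target_elements, x$seed, x$jitter
  ))
  invisible(x)
}

# superellipse cross-section of the cavity at axial fraction s in [0,1]:
# half-axes shrink linearly from the rim to the optic-canal circle and the
# exponent blends a rounded rectangle (p = 4) into a circle (p = 2)
orbit_section_point <- function(params, s, theta) {
  a <- (params$rim_width / 2) * (1 - s) + params$optic_canal_radius * s
  b <- (params$rim_height / 2) * (1 - s) + params$optic_canal_radius * s
  p <- 4 * (1 - s) + 2 * s
  ct <- cos(theta)
  st <- sin(theta)
  cbind(
    params$depth * s,
    a * sign(ct) * abs(ct)^(2 / p),
    b * sign(st) * abs(st)^(2 / p)
  )
}

# arc-length positions along the cross-section ring at axial fraction s,
# measured from the floor/lateral corner direction (theta = -3pi/4); frac
# in [0, 1) cyclic
orbit_ring_interp <- function(params, s, frac, nsamp = 720L) {
  th <- -3 * pi / 4 + 2 * pi * (0:nsamp) / nsamp
  pts <- orbit_section_point(params, s, th)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
    pts[-(nsamp + 1L), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[nsamp + 1L]
  targ <- (frac %% 1) * total
  idx <- pmin(findInterval(targ, cum, rightmost.closed = TRUE), nsamp)
  tt <- (targ - cum[idx]) / seg[idx]
  pts[idx, , drop = FALSE] +
    tt * (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE])
}

orbit_ring_perimeter <- function(params, s, nsamp = 720L) {
  th <- -3 * pi / 4 + 2 * pi * (0:nsamp) / nsamp
  pts <- orbit_section_point(params, s, th)
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
    pts[-(nsamp + 1L), , drop = FALSE])^2)))
}

# grid resolution: near-square cells at mid-depth, adjusted so the final
# count (after slit removal) lands near target_elements
orbit_grid_dims <- function(params) {
  per <- orbit_ring_perimeter(params, 0.5)
  target <- params$target_elements
  n_u <- max(12L, as.integer(round(sqrt(target / 2 * per / params$depth))))
  n_v <- max(4L, as.integer(round(target / 2 / n_u)))
  # anticipate slit removal and add rows to compensate
  rm_est <- orbit_slit_cells(params, n_u, n_v, per)
  n_v <- max(4L, as.integer(round((target + rm_est) / 2 / n_u)))
  list(n_u = n_u, n_v = n_v, perimeter_mid = per)
}

# number of grid cells the fissure slit removes (estimate = exact layout)
orbit_slit_cells <- function(params, n_u, n_v, perimeter_mid) {
  if (params$fissure_width <= 0 || params$fissure_length <= 0) return(0L)
  ncol_slit <- max(1L, as.integer(round(
    params$fissure_width / (perimeter_mid / n_u)
  )))
  rows <- orbit_slit_rows(params, n_v)
  2L * ncol_slit * length(rows)
}

# rows (1-based cell-row indices) covered by the slit: posterior third of
# the wall, never touching the rim row or the apex row
orbit_slit_rows <- function(params, n_v) {
  if (params$fissure_width <= 0 || params$fissure_length <= 0) {
    return(integer())
  }
  x0 <- 0.55 * params$depth
  x1 <- min(x0 + params$fissure_length, 0.95 * params$depth)
  rows <- which(
    (seq_len(n_v) - 0.5) / n_v * params$depth >= x0 &
      (seq_len(n_v) - 0.5) / n_v * params$depth <= x1
  )
  rows <- rows[rows >= 2L & rows <= n_v - 1L]
  rows
}

#' Generate the synthetic average-orbit shell mesh
#'
#' Builds the parametric orbit surface described in
#' \code{\link{orbit_params}} on a structured grid (two triangles per
#' cell), removes the inferior-orbital-fissure slit, labels the five wall
#' regions, assigns per-region thickness (with a thicker rim band on the
#' first element row), fixes the apex-aperture ring plus the superior rim
#' arc (roof and upper halves of the medial/lateral walls, leaving the
#' inferior rim free for the strike), selects six evenly spaced strike
#' nodes on the free inferior rim and records the anterior-floor probe
#' node.  Winding is oriented so element normals point into the orbital
#' cavity.  The whole construction is deterministic for a fixed seed.
#'
#' @param params an \code{\link{orbit_params}} object.
#' @param n_load_nodes number of strike nodes to preselect on the free
#'   inferior rim.
#' @return a \code{\link{shell_mesh}}.
#' @examples
#' mesh <- generate_orbit(orbit_params(target_elements = 300))
#' mesh_quality(mesh)
#' @export
generate_orbit <- function(params = orbit_params(), n_load_nodes = 6L) {
  stopifnot(inherits(params, "orbit_params"))
  gd <- orbit_grid_dims(params)
  n_u <- gd$n_u
  n_v <- gd$n_v

  # nodes sit at equal arc-length fractions around each ring, anchored at
  # the floor/lateral corner so the column wrapping that seam is centered
  # on it; arc-length spacing keeps cells near-uniform where the
  # superellipse flattens
  node_frac <- (seq_len(n_u) - 0.5) / n_u
  svals <- seq(0, 1, length.out = n_v + 1L)
  nodes <- matrix(0, (n_v + 1L) * n_u, 3L)
  for (iv in 0:n_v) {
    nodes[iv * n_u + seq_len(n_u), ] <-
      orbit_ring_interp(params, svals[iv + 1L], node_frac)
  }
  nid <- function(iv, j) iv * n_u + ((j - 1L) %% n_u) + 1L

  # slit cells (row, column) to drop
  slit_rows <- orbit_slit_rows(params, n_v)
  ncol_slit <- if (length(slit_rows) > 0L) {
    max(1L, as.integer(round(
      params$fissure_width / (gd$perimeter_mid / n_u)
    )))
  } else {
    0L
  }
  # seam column is column n_u (center angle -3pi/4); spread extra columns
  # alternately to both sides
  slit_cols <- if (ncol_slit > 0L) {
    offs <- c(0L, as.vector(rbind(seq_len(n_u), -seq_len(n_u))))[
      seq_len(ncol_slit)
    ]
    ((n_u - 1L + offs) %% n_u) + 1L
  } else {
    integer()
  }

  tris <- matrix(0L, 2L * n_u * n_v, 3L)
  region <- character(2L * n_u * n_v)
  rim_band <- logical(2L * n_u * n_v)
  keep <- logical(2L * n_u * n_v)
  # wall membership of each column from its mid-depth center direction,
  # normalized by the local half-axes
  mid <- orbit_ring_interp(params, 0.5, seq_len(n_u) / n_u)
  a_mid <- (params$rim_width / 2 + params$optic_canal_radius) / 2
  b_mid <- (params$rim_height / 2 + params$optic_canal_radius) / 2
  col_ang <- atan2(mid[, 3L] / b_mid, mid[, 2L] / a_mid)
  e <- 0L
  for (iv in seq_len(n_v)) {
    for (cc in seq_len(n_u)) {
      n00 <- nid(iv - 1L, cc)
      n10 <- nid(iv - 1L, cc + 1L)
      n01 <- nid(iv, cc)
      n11 <- nid(iv, cc + 1L)
      ang <- col_ang[cc]
      reg <- if (ang >= -3 * pi / 4 && ang < -pi / 4) {
        if ((iv - 0.5) / n_v <= 0.5) "floor_anterior" else "floor_posterior"
      } else if (ang >= -pi / 4 && ang < pi / 4) {
        "medial"
      } else if (ang >= pi / 4 && ang < 3 * pi / 4) {
        "roof"
      } else {
        "lateral"
      }
      drop <- (cc %in% slit_cols) && (iv %in% slit_rows)
      for (tt in 1:2) {
        e <- e + 1L
        tris[e, ] <- if (tt == 1L) c(n00, n10, n11) else c(n00, n11, n01)
        region[e] <- reg
        rim_band[e] <- iv == 1L
        keep[e] <- !drop
      }
    }
  }
  tris <- tris[keep, , drop = FALSE]
  region <- region[keep]
  rim_band <- rim_band[keep]

  # flip winding if needed so normals point toward the orbital axis
  p1 <- nodes[tris[, 1L], ]
  p2 <- nodes[tris[, 2L], ]
  p3 <- nodes[tris[, 3L], ]
  nrm <- cbind(
    (p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) -
      (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
    (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) -
      (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
    (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  )
  cen <- (p1 + p2 + p3) / 3
  toward_axis <- -(nrm[, 2] * cen[, 2] + nrm[, 3] * cen[, 3])
  if (mean(sign(toward_axis)) < 0) tris <- tris[, c(1L, 3L, 2L)]

  thickness <- unlist(params$thickness_map[region], use.names = FALSE)
  thickness[rim_band] <- params$thickness_map$rim_band

  # fixed nodes: apex-aperture ring + superior rim arc (roof plus upper
  # medial/lateral rim), leaving the inferior rim free for the strike
  rim_ids <- nid(0L, seq_len(n_u))
  apex_ids <- nid(n_v, seq_len(n_u))
  sup <- rim_ids[nodes[rim_ids, 3L] > 1e-9]
  fixed <- sort(unique(c(apex_ids, sup)))

  mesh <- shell_mesh(
    nodes, tris, thickness, region,
    fixed_nodes = fixed, params = params
  )

  # seeded jitter on nodes off the boundary loops, scaled by the shortest
  # incident edge so the construction is scale-equivariant
  if (params$jitter > 0) {
    bnd_nodes <- unique(as.vector(mesh_boundary_edges(mesh)))
    minedge <- rep(Inf, nrow(nodes))
    ed <- mesh_edges(mesh)
    el <- sqrt(rowSums((nodes[ed[, 1L], ] - nodes[ed[, 2L], ])^2))
    for (k in seq_len(nrow(ed))) {
      if (el[k] < minedge[ed[k, 1L]]) minedge[ed[k, 1L]] <- el[k]
      if (el[k] < minedge[ed[k, 2L]]) minedge[ed[k, 2L]] <- el[k]
    }
    set.seed(params$seed)
    disp <- matrix(runif(3L * nrow(nodes), -1, 1), ncol = 3L)
    disp <- disp / sqrt(3)
    movable <- setdiff(seq_len(nrow(nodes)), bnd_nodes)
    nodes[movable, ] <- nodes[movable, ] +
      params$jitter * minedge[movable] * disp[movable, ]
    mesh$nodes <- nodes
  }

  # quality gate
  qual <- mesh_quality(mesh)
  if (qual$min_angle_deg <= 10) {
    bad <- worst_angle_element(mesh)
    stop(sprintf(
      "mesh generation failed: triangle %d has internal angle %.2f deg",
      bad$element, bad$angle
    ), call. = FALSE)
  }
  n_el <- nrow(mesh$triangles)
  if (abs(n_el - params$target_elements) > 0.1 * params$target_elements) {
    stop(sprintf(
      "mesh generation failed: %d elements, more than 10%% away from target %d",
      n_el, params$target_elements
    ), call. = FALSE)
  }

  mesh$load_nodes <- select_load_nodes(mesh, n_load_nodes)
  mesh$probe_A <- orbit_probe_node(mesh, params)
  mesh
}

worst_angle_element <- function(mesh) {
  tr <- mesh$triangles
  p <- mesh$nodes
  worst <- list(element = NA_integer_, angle = Inf)
  for (k in 1:3) {
    a <- p[tr[, k], , drop = FALSE]
    b <- p[tr[, k %% 3L + 1L], , drop = FALSE]
    cc <- p[tr[, (k + 1L) %% 3L + 1L], , drop = FALSE]
    u <- b - a
    v <- cc - a
    ang <- acos(pmin(1, pmax(
      -1, rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
    ))) * 180 / pi
    if (min(ang) < worst$angle) {
      worst$angle <- min(ang)
      worst$element <- which.min(ang)
    }
  }
  worst
}

# ordered node cycles of every boundary loop
boundary_loops <- function(mesh) {
  be <- mesh_boundary_edges(mesh)
  if (nrow(be) == 0L) return(list())
  nxt <- split(seq_len(nrow(be)), be[, 1L])
  seen <- rep(FALSE, nrow(be))
  loops <- list()
  for (start in seq_len(nrow(be))) {
    if (seen[start]) next
    cyc <- integer()
    cur <- start
    repeat {
      seen[cur] <- TRUE
      cyc <- c(cyc, unname(be[cur, 1L]))
      cand <- nxt[[as.character(be[cur, 2L])]]
      cand <- cand[!seen[cand]]
      if (length(cand) == 0L) break
      cur <- cand[1L]
    }
    loops[[length(loops) + 1L]] <- cyc
  }
  loops
}

#' Select evenly spaced strike nodes on the free inferior rim
#'
#' Finds the rim boundary loop (the loop with the most anterior mean
#' position), restricts it to nodes left unconstrained, and picks \code{n}
#' nodes approximately equally spaced by arc length along that free arc.
#'
#' @param mesh a \code{\link{shell_mesh}}.
#' @param n number of strike nodes.
#' @return integer vector of \code{n} node indices, ordered along the arc.
#' @export
select_load_nodes <- function(mesh, n = 6L) {
  stopifnot(n >= 1L)
  loops <- boundary_loops(mesh)
  if (length(loops) == 0L) stop("mesh has no boundary", call. = FALSE)
  mean_x <- vapply(loops, function(l) mean(mesh$nodes[l, 1L]), numeric(1))
  rim <- loops[[which.min(mean_x)]]
  free <- !(rim %in% mesh$fixed_nodes)
  if (!any(free)) stop("no free inferior rim arc", call. = FALSE)
  # rotate the cycle so the free arc is contiguous from its start
  if (all(free)) {
    arc <- rim
  } else {
    k <- length(rim)
    start <- which(free & !c(free[k], free[-k]))[1L]
    ord <- ((start - 1L + seq_len(k) - 1L) %% k) + 1L
    arc <- rim[ord][free[ord]]
  }
  if (length(arc) < n) {
    stop(sprintf(
      "only %d candidate rim nodes for %d load nodes", length(arc), n
    ), call. = FALSE)
  }
  pts <- mesh$nodes[arc, , drop = FALSE]
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
    pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  nc <- length(arc)
  if (n == 1L) {
    return(arc[which.min(abs(cum - total / 2))])
  }
  # dynamic program for a given target gap g: minimize squared gap
  # deviation with weakly weighted end margins, so the picks stay both
  # evenly spaced and spread over the arc
  solve_for_gap <- function(g) {
    margin <- max(0, (total - (n - 1L) * g) / 2)
    wm <- 0.25
    dp <- matrix(Inf, nc, n)
    back <- matrix(0L, nc, n)
    dp[, 1L] <- wm * (cum - margin)^2
    for (k in 2:n) {
      for (j in k:nc) {
        prev <- (k - 1L):(j - 1L)
        costs <- dp[prev, k - 1L] + (cum[j] - cum[prev] - g)^2
        b <- which.min(costs)
        dp[j, k] <- costs[b]
        back[j, k] <- prev[b]
      }
    }
    final <- dp[, n] + wm * (total - cum - margin)^2
    j <- which.min(final)
    sel <- integer(n)
    for (k in n:1) {
      sel[k] <- j
      j <- back[j, k]
    }
    sel
  }
  # sweep the gap target and keep the selection with the most uniform
  # realized spacing (ties broken toward wider coverage of the arc)
  best <- NULL
  best_score <- Inf
  for (gfrac in seq(0.55, 1.05, by = 0.025)) {
    sel <- solve_for_gap(gfrac * total / n)
    gaps <- diff(cum[sel])
    dev <- max(abs(gaps - mean(gaps))) / mean(gaps)
    span <- (cum[sel[n]] - cum[sel[1L]]) / total
    score <- dev + max(0, 0.6 - span)
    if (score < best_score - 1e-12) {
      best_score <- score
      best <- sel
    }
  }
  arc[best]
}

# anterior-floor probe: node nearest the surface point at 25% depth midway
# between the nasolacrimal (medial-floor) corner and the infraorbital
# midline, restricted to floor nodes that are neither fixed nor loaded
orbit_probe_node <- function(mesh, params) {
  target <- orbit_section_point(params, 0.25, -3 * pi / 8)
  floor_el <- mesh$region %in% c("floor_anterior", "floor_posterior")
  cand <- setdiff(
    unique(as.vector(mesh$triangles[floor_el, ])),
    c(mesh$fixed_nodes, mesh$load_nodes)
  )
  d2 <- rowSums((mesh$nodes[cand, , drop = FALSE] -
    matrix(target, length(cand), 3L, byrow = TRUE))^2)
  cand[which.min(d2)]
}
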