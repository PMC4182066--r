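#' Triangulated shell mesh
#'
#' Container for a triangulated shell surface with per-element thickness
#' and region labels plus the node sets the simulation needs: fixed
#' (fully constrained) nodes, ordered load nodes and an optional probe
#' node.  Triangle winding is expected to be globally consistent, with the
#' right-hand normal pointing toward the reference "interior" side (for the
#' orbit model: into the orbital cavity).
#'
#' @param nodes numeric n x 3 matrix of coordinates (mm).
#' @param triangles integer m x 3 matrix of 1-based node indices.
#' @param thickness per-element thickness (mm); recycled if scalar.
#' @param region per-element character labels; recycled if scalar.
#' @param fixed_nodes integer vector of fully constrained nodes.
#' @param load_nodes ordered integer vector of strike nodes.
#' @param probe_A single node index used for displacement probing (or NA).
#' @param params optional generator parameter list kept for provenance.
#' @return object of class \code{shell_mesh}.
#' @seealso \code{\link{generate_orbit}}, \code{\link{mesh_quality}}
#' @export
shell_mesh <- function(nodes, triangles, thickness, region = "wall",
                       fixed_nodes = integer(), load_nodes = integer(),
                       probe_A = NA_integer_, params = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix", call. = FALSE)
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix", call. = FALSE)
  m <- nrow(triangles)
  if (min(triangles) < 1L || max(triangles) > nrow(nodes)) {
    stop("triangle indices out of range", call. = FALSE)
  }
  thickness <- rep_len(as.numeric(thickness), m)
  region <- rep_len(as.character(region), m)
  if (any(thickness <= 0)) stop("thicknesses must be positive", call. = FALSE)
  fixed_nodes <- sort(unique(as.integer(fixed_nodes)))
  load_nodes <- unname(as.integer(load_nodes))
  if (length(intersect(load_nodes, fixed_nodes)) > 0L) {
    stop("load nodes and fixed nodes must be disjoint", call. = FALSE)
  }
  if (!is.na(probe_A) && probe_A %in% fixed_nodes) {
    stop("probe node must not be fixed", call. = FALSE)
  }
  structure(
    list(
      nodes = nodes, triangles = triangles, thickness = thickness,
      region = region, fixed_nodes = fixed_nodes, load_nodes = load_nodes,
      probe_A = as.integer(probe_A), params = params
    ),
    class = "shell_mesh"
  )
}

#' @export
print.shell_mesh <- function(x, ...) {
  cat(sprintf(
    "Shell mesh: %d nodes, %d triangles\n",
    nrow(x$nodes), nrow(x$triangles)
  ))
  cat("  regions:", paste(sprintf(
    "%s (%d)", names(table(x$region)), as.integer(table(x$region))
  ), collapse = ", "), "\n")
  cat(sprintf(
    "  fixed nodes: %d; load nodes: %d; probe A: %s\n",
    length(x$fixed_nodes), length(x$load_nodes),
    ifelse(is.na(x$probe_A), "none", x$probe_A)
  ))
  invisible(x)
}

# per-element areas and unit normals (winding normal)
mesh_element_geometry <- function(mesh) {
  p1 <- mesh$nodes[mesh$triangles[, 1L], , drop = FALSE]
  p2 <- mesh$nodes[mesh$triangles[, 2L], , drop = FALSE]
  p3 <- mesh$nodes[mesh$triangles[, 3L], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  nx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  ny <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  nz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  a2 <- sqrt(nx^2 + ny^2 + nz^2)
  list(
    area = a2 / 2,
    normal = cbind(nx, ny, nz) / a2,
    centroid = (p1 + p2 + p3) / 3
  )
}

#' Area-weighted node normals
#'
#' Unit node normals averaged (area-weighted) over incident elements,
#' pointing to the same side as the element winding normals -- into the
#' cavity for orbit meshes.  These are the projection axes of
#' \code{\link{signed_wall_displacement}}.
#'
#' @param mesh a \code{\link{shell_mesh}}.
#' @return n x 3 matrix of unit vectors (zero rows for isolated nodes).
#' @export
mesh_node_normals <- function(mesh) {
  ge <- mesh_element_geometry(mesh)
  nn <- matrix(0, nrow(mesh$nodes), 3L)
  for (k in 1:3) {
    idx <- mesh$triangles[, k]
    for (c in 1:3) {
      nn[, c] <- nn[, c] + unname(tapply_add(
        ge$normal[, c] * ge$area, idx, nrow(mesh$nodes)
      ))
    }
  }
  len <- sqrt(rowSums(nn^2))
  len[len == 0] <- 1
  nn / len
}

# fast grouped sum returning a dense length-n vector
tapply_add <- function(values, index, n) {
  out <- numeric(n)
  s <- rowsum(values, group = index, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# directed edge table: one row per triangle edge (3m rows)
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  from <- c(tr[, 1L], tr[, 2L], tr[, 3L])
  to <- c(tr[, 2L], tr[, 3L], tr[, 1L])
  cbind(from = from, to = to)
}

# boundary edges = undirected edges used by exactly one triangle
mesh_boundary_edges <- function(mesh) {
  ed <- mesh_edges(mesh)
  key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  cnt <- table(key)
  ed[cnt[key] == 1L, , drop = FALSE]
}

# count closed loops among boundary edges by adjacency traversal
count_boundary_loops <- function(mesh) {
  be <- mesh_boundary_edges(mesh)
  if (nrow(be) == 0L) return(0L)
  nxt <- split(seq_len(nrow(be)), be[, 1L])
  seen <- rep(FALSE, nrow(be))
  loops <- 0L
  for (start in seq_len(nrow(be))) {
    if (seen[start]) next
    loops <- loops + 1L
    cur <- start
    repeat {
      seen[cur] <- TRUE
      cand <- nxt[[as.character(be[cur, 2L])]]
      cand <- cand[!seen[cand]]
      if (length(cand) == 0L) break
      cur <- cand[1L]
    }
  }
  loops
}

#' Mesh quality and topology report
#'
#' Pure report: internal-angle range, aspect-ratio summary, boundary-loop
#' count, Euler characteristic and whether the triangle winding is globally
#' consistent (every interior edge traversed once in each direction).
#'
#' @param mesh a \code{\link{shell_mesh}}.
#' @return list of class \code{mesh_quality} with fields
#'   \code{min_angle_deg}, \code{max_angle_deg}, \code{aspect_ratio}
#'   (summary stats), \code{boundary_loops}, \code{euler_characteristic},
#'   \code{orientation_consistent}, \code{n_nodes}, \code{n_elements}.
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "shell_mesh"), nrow(mesh$triangles) > 0L)
  tr <- mesh$triangles
  p <- mesh$nodes
  ang <- matrix(0, nrow(tr), 3L)
  lens <- matrix(0, nrow(tr), 3L)
  for (k in 1:3) {
    a <- p[tr[, k], , drop = FALSE]
    b <- p[tr[, k %% 3L + 1L], , drop = FALSE]
    cc <- p[tr[, (k + 1L) %% 3L + 1L], , drop = FALSE]
    u <- b - a
    v <- cc - a
    cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
    ang[, k] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    lens[, k] <- sqrt(rowSums((b - cc)^2))
  }
  ge <- mesh_element_geometry(mesh)
  # longest edge / (2 * inradius), 1 for equilateral
  s <- rowSums(lens) / 2
  inradius <- ge$area / s
  aspect <- apply(lens, 1L, max) / (2 * sqrt(3) * inradius)

  ed <- mesh_edges(mesh)
  key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  cnt <- table(key)
  manifold <- all(cnt <= 2L)
  # orientation consistent iff no directed edge repeats
  dirkey <- paste(ed[, 1L], ed[, 2L])
  oriented <- manifold && !anyDuplicated(dirkey)

  structure(
    list(
      n_nodes = nrow(p),
      n_elements = nrow(tr),
      min_angle_deg = min(ang),
      max_angle_deg = max(ang),
      aspect_ratio = summary(aspect),
      boundary_loops = count_boundary_loops(mesh),
      euler_characteristic = nrow(p) - length(cnt) + nrow(tr),
      edge_manifold = manifold,
      orientation_consistent = oriented
    ),
    class = "mesh_quality"
  )
}

#' @export
print.mesh_quality <- function(x, ...) {
  cat("Mesh quality report\n")
  cat(sprintf("  nodes/elements: %d / %d\n", x$n_nodes, x$n_elements))
  cat(sprintf(
    "  internal angles: %.1f - %.1f deg\n", x$min_angle_deg, x$max_angle_deg
  ))
  cat(sprintf(
    "  boundary loops: %d, Euler characteristic: %d\n",
    x$boundary_loops, x$euler_characteristic
  ))
  cat(sprintf(
    "  edge-manifold: %s, orientation-consistent: %s\n",
    x$edge_manifold, x$orientation_consistent
  ))
  invisible(x)
}
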