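#' Mesh file exchange
#'
#' \code{write_mesh}/\code{read_mesh} exchange a \code{\link{shell_mesh}}
#' as Gmsh MSH 4.1 ASCII (\code{.msh}) or legacy ASCII VTK unstructured
#' grid (\code{.vtk}).  Both carry the element data \code{thickness} (mm)
#' and \code{region} (integer code) and the node data \code{fixed},
#' \code{load} (1-based strike order, 0 elsewhere) and \code{probe_A}.
#' Region labels use the canonical code table (1 floor_anterior,
#' 2 floor_posterior, 3 medial, 4 roof, 5 lateral); other labels are coded
#' from 6 upward in sorted order and read back as \code{region_<code>}.
#'
#' @param mesh a \code{\link{shell_mesh}}.
#' @param path file path ending in \code{.msh} or \code{.vtk}.
#' @return \code{write_mesh} returns \code{path} invisibly;
#'   \code{read_mesh} returns a \code{\link{shell_mesh}}.
#' @name mesh-io
NULL

.region_codes <- c(
  floor_anterior = 1L, floor_posterior = 2L, medial = 3L, roof = 4L,
  lateral = 5L
)

region_to_code <- function(region) {
  code <- unname(.region_codes[region])
  if (anyNA(code)) {
    extra <- sort(unique(region[is.na(code)]))
    code[is.na(code)] <- 5L + match(region[is.na(code)], extra)
  }
  code
}

code_to_region <- function(code) {
  out <- names(.region_codes)[match(code, .region_codes)]
  out[is.na(out)] <- paste0("region_", code[is.na(out)])
  out
}

mesh_node_marks <- function(mesh) {
  n <- nrow(mesh$nodes)
  fixed <- integer(n)
  fixed[mesh$fixed_nodes] <- 1L
  load <- integer(n)
  load[mesh$load_nodes] <- seq_along(mesh$load_nodes)
  probe <- integer(n)
  if (!is.na(mesh$probe_A)) probe[mesh$probe_A] <- 1L
  list(fixed = fixed, load = load, probe_A = probe)
}

marks_to_sets <- function(fixed, load, probe) {
  li <- which(load != 0L)
  list(
    fixed_nodes = which(fixed != 0L),
    load_nodes = li[order(load[li])],
    probe_A = if (any(probe != 0L)) which(probe != 0L)[1L] else NA_integer_
  )
}

#' @rdname mesh-io
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "shell_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    vtk = write_mesh_vtk(mesh, path),
    msh = write_mesh_msh(mesh, path),
    stop("unsupported mesh format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' @rdname mesh-io
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    vtk = read_mesh_vtk(path),
    msh = read_mesh_msh(path),
    stop("unsupported mesh format: .", ext, call. = FALSE)
  )
}

fmt_num <- function(x) sprintf("%.17g", x)

write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$triangles)
  marks <- mesh_node_marks(mesh)
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("orbishock shell mesh")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", n, " double")
  writeLines(apply(mesh$nodes, 1L, function(r) {
    paste(fmt_num(r), collapse = " ")
  }), con)
  wl("CELLS ", m, " ", 4L * m)
  writeLines(apply(mesh$triangles - 1L, 1L, function(r) {
    paste(c(3L, r), collapse = " ")
  }), con)
  wl("CELL_TYPES ", m)
  writeLines(rep("5", m), con)
  wl("CELL_DATA ", m)
  wl("SCALARS thickness double 1")
  wl("LOOKUP_TABLE default")
  writeLines(fmt_num(mesh$thickness), con)
  wl("SCALARS region int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(region_to_code(mesh$region)), con)
  wl("POINT_DATA ", n)
  for (nm in c("fixed", "load", "probe_A")) {
    wl("SCALARS ", nm, " int 1")
    wl("LOOKUP_TABLE default")
    writeLines(as.character(marks[[nm]]), con)
  }
  invisible(path)
}

read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1L]]
  ip <- grep("^POINTS", lines)
  if (length(ip) != 1L) stop("malformed VTK: no POINTS section", call. = FALSE)
  n <- as.integer(toks(lines[ip])[2L])
  coords <- as.numeric(unlist(strsplit(
    trimws(lines[(ip + 1L):(ip + n)]), "\\s+"
  )))
  nodes <- matrix(coords, ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", lines)
  m <- as.integer(toks(lines[ic])[2L])
  cells <- do.call(rbind, lapply(lines[(ic + 1L):(ic + m)], function(s) {
    v <- as.integer(toks(s))
    if (v[1L] != 3L) stop("VTK reader supports triangles only", call. = FALSE)
    v[2:4] + 1L
  }))
  scalar <- function(name, where, count) {
    i <- grep(paste0("^SCALARS ", name, " "), lines)
    i <- i[i > where]
    if (length(i) == 0L) {
      stop("VTK file lacks required field '", name, "'", call. = FALSE)
    }
    as.numeric(lines[(i[1L] + 2L):(i[1L] + 1L + count)])
  }
  icd <- grep("^CELL_DATA", lines)[1L]
  ipd <- grep("^POINT_DATA", lines)[1L]
  if (is.na(icd)) stop("VTK file lacks CELL_DATA", call. = FALSE)
  thickness <- scalar("thickness", icd, m)
  region <- code_to_region(as.integer(scalar("region", icd, m)))
  if (is.na(ipd)) stop("VTK file lacks POINT_DATA", call. = FALSE)
  sets <- marks_to_sets(
    as.integer(scalar("fixed", ipd, n)),
    as.integer(scalar("load", ipd, n)),
    as.integer(scalar("probe_A", ipd, n))
  )
  shell_mesh(
    nodes, cells, thickness, region,
    fixed_nodes = sets$fixed_nodes, load_nodes = sets$load_nodes,
    probe_A = sets$probe_A
  )
}

write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$triangles)
  marks <- mesh_node_marks(mesh)
  wl <- function(...) writeLines(paste0(...), con)
  wl("$MeshFormat")
  wl("4.1 0 8")
  wl("$EndMeshFormat")
  wl("$Entities")
  wl("0 0 1 0")
  bb <- apply(mesh$nodes, 2L, range)
  wl(paste(
    1L, fmt_num(bb[1L, 1L]), fmt_num(bb[1L, 2L]), fmt_num(bb[1L, 3L]),
    fmt_num(bb[2L, 1L]), fmt_num(bb[2L, 2L]), fmt_num(bb[2L, 3L]), 0L, 0L
  ))
  wl("$EndEntities")
  wl("$Nodes")
  wl(paste(1L, n, 1L, n))
  wl(paste(2L, 1L, 0L, n))
  writeLines(as.character(seq_len(n)), con)
  writeLines(apply(mesh$nodes, 1L, function(r) {
    paste(fmt_num(r), collapse = " ")
  }), con)
  wl("$EndNodes")
  wl("$Elements")
  wl(paste(1L, m, 1L, m))
  wl(paste(2L, 1L, 2L, m))
  writeLines(vapply(seq_len(m), function(e) {
    paste(c(e, mesh$triangles[e, ]), collapse = " ")
  }, character(1)), con)
  wl("$EndElements")
  elem_data <- function(name, values) {
    wl("$ElementData")
    wl("1")
    wl("\"", name, "\"")
    wl("1")
    wl("0")
    wl("3")
    wl("0")
    wl("1")
    wl(as.character(m))
    writeLines(paste(seq_len(m), fmt_num(values)), con)
    wl("$EndElementData")
  }
  node_data <- function(name, values) {
    wl("$NodeData")
    wl("1")
    wl("\"", name, "\"")
    wl("1")
    wl("0")
    wl("3")
    wl("0")
    wl("1")
    wl(as.character(n))
    writeLines(paste(seq_len(n), fmt_num(values)), con)
    wl("$EndNodeData")
  }
  elem_data("thickness", mesh$thickness)
  elem_data("region", region_to_code(mesh$region))
  node_data("fixed", marks$fixed)
  node_data("load", marks$load)
  node_data("probe_A", marks$probe_A)
  invisible(path)
}

read_mesh_msh <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- which(lines == paste0("$", name))
    i1 <- which(lines == paste0("$End", name))
    if (length(i0) == 0L || length(i1) == 0L) return(NULL)
    mapply(function(a, b) lines[(a + 1L):(b - 1L)], i0, i1, SIMPLIFY = FALSE)
  }
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1L]]
  ns <- sect("Nodes")
  if (is.null(ns)) stop("malformed MSH: no $Nodes", call. = FALSE)
  ns <- ns[[1L]]
  hdr <- as.integer(toks(ns[1L]))
  n <- hdr[2L]
  # single block layout as written by write_mesh
  tags <- as.integer(ns[3:(2L + n)])
  coords <- do.call(rbind, lapply(ns[(3L + n):(2L + 2L * n)], function(s) {
    as.numeric(toks(s))
  }))
  nodes <- matrix(0, n, 3L)
  nodes[tags, ] <- coords[, 1:3]
  es <- sect("Elements")
  if (is.null(es)) stop("malformed MSH: no $Elements", call. = FALSE)
  es <- es[[1L]]
  m <- as.integer(toks(es[1L]))[2L]
  etype <- as.integer(toks(es[2L]))[3L]
  if (etype != 2L) stop("MSH reader supports 3-node triangles only", call. = FALSE)
  rows <- do.call(rbind, lapply(es[3:(2L + m)], function(s) {
    as.integer(toks(s))
  }))
  tris <- matrix(0L, m, 3L)
  tris[rows[, 1L], ] <- rows[, 2:4]
  named_data <- function(blocks) {
    out <- list()
    for (b in blocks) {
      nm <- gsub("\"", "", b[2L])
      cnt <- as.integer(b[8L])
      vals <- do.call(rbind, lapply(b[9:(8L + cnt)], function(s) {
        as.numeric(toks(s))
      }))
      v <- numeric(cnt)
      v[as.integer(vals[, 1L])] <- vals[, 2L]
      out[[nm]] <- v
    }
    out
  }
  ed <- named_data(sect("ElementData") %||% list())
  nd <- named_data(sect("NodeData") %||% list())
  for (req in c("thickness", "region")) {
    if (is.null(ed[[req]])) {
      stop("MSH file lacks required element field '", req, "'", call. = FALSE)
    }
  }
  for (req in c("fixed", "load", "probe_A")) {
    if (is.null(nd[[req]])) {
      stop("MSH file lacks required node field '", req, "'", call. = FALSE)
    }
  }
  sets <- marks_to_sets(
    as.integer(nd$fixed), as.integer(nd$load), as.integer(nd$probe_A)
  )
  shell_mesh(
    nodes, tris, ed$thickness, code_to_region(as.integer(ed$region)),
    fixed_nodes = sets$fixed_nodes, load_nodes = sets$load_nodes,
    probe_A = sets$probe_A
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write orbit generator parameters as YAML
#'
#' Flat key/value file mirroring the \code{\link{orbit_params}} fields
#' (thicknesses nested under \code{thickness_map}).
#'
#' @param path YAML file path.
#' @param params an \code{orbit_params} object.
#' @return \code{read_orbit_params} returns an \code{orbit_params};
#'   \code{write_orbit_params} returns \code{path} invisibly.
#' @export
read_orbit_params <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(orbit_params, vals)
}

#' @rdname read_orbit_params
#' @export
write_orbit_params <- function(params, path) {
  stopifnot(inherits(params, "orbit_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
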