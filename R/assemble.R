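#' Global assembly of the shell finite-element system
#'
#' Assembles the sparse symmetric stiffness matrix and the diagonal lumped
#' mass for a \code{\link{shell_mesh}}, using 6 generalized displacements
#' per node (3 translations in mm, 3 rotations in rad) in the internal
#' mm-N-tonne-s unit system.  All 6 dofs of every node in
#' \code{mesh$fixed_nodes} are constrained.
#'
#' @param mesh a \code{\link{shell_mesh}}.
#' @param material a \code{\link{material}}.
#' @param drilling_factor passed to \code{\link{element_stiffness}}.
#' @return object of class \code{global_system}: list with \code{K}
#'   (sparse symmetric stiffness, ndof x ndof), \code{M} (numeric diagonal
#'   mass vector), \code{ndof}, \code{constrained_dofs}, \code{free_dofs},
#'   \code{mesh} and \code{material}.
#' @export
assemble <- function(mesh, material, drilling_factor = 1e-4) {
  stopifnot(inherits(mesh, "shell_mesh"), inherits(material, "material"))
  ntri <- nrow(mesh$triangles)
  nnode <- nrow(mesh$nodes)
  ndof <- 6L * nnode
  ii <- integer(324L * ntri)
  jj <- integer(324L * ntri)
  xx <- numeric(324L * ntri)
  pos <- 0L
  template <- as.matrix(expand.grid(a = 1:18, b = 1:18))
  for (e in seq_len(ntri)) {
    tri <- mesh$triangles[e, ]
    Ke <- tryCatch(
      element_stiffness(
        mesh$nodes[tri, , drop = FALSE], mesh$thickness[e], material,
        drilling_factor
      ),
      error = function(err) {
        stop(sprintf("element %d: %s", e, conditionMessage(err)), call. = FALSE)
      }
    )
    edofs <- as.vector(vapply(
      tri, function(n) 6L * (n - 1L) + 1:6, integer(6)
    ))
    idx <- pos + seq_len(324L)
    ii[idx] <- edofs[template[, 1L]]
    jj[idx] <- edofs[template[, 2L]]
    xx[idx] <- Ke
    pos <- pos + 324L
  }
  K <- Matrix::sparseMatrix(
    i = ii, j = jj, x = xx, dims = c(ndof, ndof), symmetric = FALSE
  )
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  M <- lumped_mass(mesh, material)
  constrained <- sort(as.vector(vapply(
    mesh$fixed_nodes, function(n) 6L * (n - 1L) + 1:6, integer(6)
  )))
  structure(
    list(
      K = K, M = M, ndof = ndof,
      constrained_dofs = constrained,
      free_dofs = setdiff(seq_len(ndof), constrained),
      mesh = mesh, material = material
    ),
    class = "global_system"
  )
}

#' @export
print.global_system <- function(x, ...) {
  cat(sprintf(
    "Assembled shell system: %d dofs (%d constrained), %d elements\n",
    x$ndof, length(x$constrained_dofs), nrow(x$mesh$triangles)
  ))
  invisible(x)
}

#' Diagonal (lumped) mass vector
#'
#' Each element distributes its mass rho*area*thickness equally to its
#' three nodes on the translational dofs.  Rotational dofs receive the
#' nodal mass share scaled by area/12 (tonne mm^2), a standard
#' element-size-based rotary-inertia lumping that keeps the rotational
#' eigenfrequencies from controlling the explicit stable time step.
#'
#' @param mesh a \code{\link{shell_mesh}}.
#' @param material a \code{\link{material}}.
#' @return numeric vector of length 6 * n_nodes (tonne on translations,
#'   tonne mm^2 on rotations).
#' @export
lumped_mass <- function(mesh, material) {
  stopifnot(inherits(mesh, "shell_mesh"), inherits(material, "material"))
  ge <- mesh_element_geometry(mesh)
  me <- material$rho * ge$area * mesh$thickness # tonnes
  nnode <- nrow(mesh$nodes)
  mt <- numeric(nnode)
  mr <- numeric(nnode)
  for (k in 1:3) {
    idx <- mesh$triangles[, k]
    mt <- mt + tapply_add(me / 3, idx, nnode)
    mr <- mr + tapply_add(me / 3 * ge$area / 12, idx, nnode)
  }
  M <- numeric(6L * nnode)
  for (c in 1:3) M[seq(c, by = 6L, length.out = nnode)] <- mt
  for (c in 4:6) M[seq(c, by = 6L, length.out = nnode)] <- mr
  M
}

#' Static solution of the constrained system
#'
#' Solves K u = f on the free dofs by sparse Cholesky factorization and
#' verifies the residual.
#'
#' @param system a \code{global_system}.
#' @param load numeric force vector of length \code{system$ndof}
#'   (N on translations, N mm on rotations).
#' @param rel_tol residual acceptance threshold relative to \code{||f||}.
#' @return displacement vector of length \code{ndof} (mm / rad); zero on
#'   constrained dofs.
#' @export
static_solve <- function(system, load, rel_tol = 1e-8) {
  stopifnot(inherits(system, "global_system"), length(load) == system$ndof)
  free <- system$free_dofs
  u <- numeric(system$ndof)
  f <- load[free]
  if (all(f == 0)) return(u)
  Kff <- system$K[free, free]
  uf <- tryCatch(
    as.numeric(Matrix::solve(Kff, f, sparse = TRUE)),
    error = function(err) {
      stop(
        "singular stiffness: the constrained system still admits ",
        "rigid-body or mechanism modes (check fixed_nodes); solver said: ",
        conditionMessage(err),
        call. = FALSE
      )
    }
  )
  res <- sqrt(sum((as.numeric(Kff %*% uf) - f)^2)) / sqrt(sum(f^2))
  if (!is.finite(res) || res > rel_tol) {
    stop(sprintf(
      paste(
        "static solve residual %.3g exceeds tolerance %.3g;",
        "the constrained system is singular or nearly so and likely",
        "retains rigid-body or mechanism modes (check fixed_nodes)"
      ),
      res, rel_tol
    ), call. = FALSE)
  }
  u[free] <- uf
  u
}

#' Export system matrices to MatrixMarket files
#'
#' Debug helper: writes the stiffness (sparse) and mass (diagonal) of an
#' assembled system as MatrixMarket files \code{stiffness.mtx} and
#' \code{mass.mtx} in \code{dir}.
#'
#' @param system a \code{global_system}.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
export_system_mtx <- function(system, dir) {
  stopifnot(inherits(system, "global_system"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kfile <- file.path(dir, "stiffness.mtx")
  mfile <- file.path(dir, "mass.mtx")
  Matrix::writeMM(as(system$K, "generalMatrix"), kfile)
  Matrix::writeMM(Matrix::Diagonal(x = system$M), mfile)
  invisible(c(kfile, mfile))
}
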