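#' Surface stress recovery
#'
#' Recovers per-element surface stresses at each snapshot from the shell
#' kinematics: membrane strain from the CST field at the element, curvature
#' from the DKT field at the centroid, and fiber stresses
#' sigma = D (eps_membrane +/- (t/2) kappa) via the plane-stress law.  The
#' "top" fiber is the surface on the element-normal side (toward the
#' orbital interior for orbit meshes).
#'
#' @param history a \code{displacement_history}.
#' @param mesh the mesh of the run.
#' @param material the run material.
#' @return object of class \code{stress_field}: list with \code{times},
#'   \code{von_mises_top}, \code{von_mises_bottom} (n_elements x
#'   n_snapshots, MPa) and \code{sigma_top}, \code{sigma_bottom} (3 x
#'   n_elements x n_snapshots arrays of sigma_x, sigma_y, tau_xy in the
#'   element frame).
#' @export
recover_stress <- function(history, mesh, material) {
  nnode <- nrow(mesh$nodes)
  if (nrow(history$U) != 6L * nnode) {
    stop("history and mesh node counts disagree", call. = FALSE)
  }
  ntri <- nrow(mesh$triangles)
  nsnap <- length(history$times)
  D <- plane_stress_D(material$E_mpa, material$poisson)
  vm <- function(sig) {
    sqrt(pmax(
      0,
      sig[1L, ]^2 - sig[1L, ] * sig[2L, ] + sig[2L, ]^2 + 3 * sig[3L, ]^2
    ))
  }
  von_top <- matrix(0, ntri, nsnap)
  von_bot <- matrix(0, ntri, nsnap)
  sig_top <- array(0, c(3L, ntri, nsnap))
  sig_bot <- array(0, c(3L, ntri, nsnap))
  mem <- as.vector(vapply(0:2, function(i) 6L * i + c(1L, 2L), integer(2)))
  bnd <- as.vector(vapply(0:2, function(i) 6L * i + c(3L, 4L, 5L), integer(3)))
  for (e in seq_len(ntri)) {
    tri <- mesh$triangles[e, ]
    fr <- tri_local_frame(mesh$nodes[tri, , drop = FALSE])
    Bm <- cst_bmatrix(fr$xy)
    Bb <- dkt_bmatrix(fr$xy, 1 / 3, 1 / 3)
    T6 <- kronecker(diag(6L), fr$R)
    edofs <- as.vector(vapply(tri, function(n) 6L * (n - 1L) + 1:6, integer(6)))
    uloc <- T6 %*% history$U[edofs, , drop = FALSE]
    eps_m <- D %*% (Bm %*% uloc[mem, , drop = FALSE])
    kap <- D %*% (Bb %*% uloc[bnd, , drop = FALSE])
    half_t <- mesh$thickness[e] / 2
    st <- eps_m + half_t * kap
    sb <- eps_m - half_t * kap
    sig_top[, e, ] <- st
    sig_bot[, e, ] <- sb
    von_top[e, ] <- vm(st)
    von_bot[e, ] <- vm(sb)
  }
  structure(
    list(
      times = history$times,
      von_mises_top = von_top, von_mises_bottom = von_bot,
      sigma_top = sig_top, sigma_bottom = sig_bot
    ),
    class = "stress_field"
  )
}

#' von Mises equivalent of a 2D (plane) stress state
#'
#' @param sigma_x,sigma_y,tau_xy stress components (MPa).
#' @return von Mises stress (MPa).
#' @export
von_mises_2d <- function(sigma_x, sigma_y, tau_xy) {
  sqrt(pmax(0, sigma_x^2 - sigma_x * sigma_y + sigma_y^2 + 3 * tau_xy^2))
}

#' First stress-limit exceedance in the orbital floor
#'
#' Scans the floor-region elements for the earliest snapshot at which the
#' von Mises stress of either surface fiber exceeds the limit.  The
#' simulation does not model the fracture itself; this reports when the
#' fracture-threshold surrogate is first crossed.
#'
#' @param stress a \code{\link{recover_stress}} result.
#' @param limit von Mises limit (MPa).
#' @param mesh the mesh of the run (for region labels).
#' @param regions regions scanned.
#' @return list with \code{time} (s or NA), \code{element}, \code{region},
#'   \code{von_mises} (MPa at the attaining element/time).
#' @export
first_exceedance <- function(stress, limit, mesh,
                             regions = c("floor_anterior", "floor_posterior")) {
  stopifnot(limit > 0)
  sel <- which(mesh$region %in% regions)
  vmax <- pmax(
    stress$von_mises_top[sel, , drop = FALSE],
    stress$von_mises_bottom[sel, , drop = FALSE]
  )
  over <- vmax > limit
  if (!any(over)) {
    return(list(
      time = NA_real_, element = NA_integer_, region = NA_character_,
      von_mises = NA_real_
    ))
  }
  k0 <- min(which(apply(over, 2L, any)))
  rows <- which(over[, k0])
  e0 <- sel[rows[which.max(vmax[rows, k0])]]
  list(
    time = stress$times[k0],
    element = e0,
    region = mesh$region[e0],
    von_mises = max(vmax[rows, k0])
  )
}
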