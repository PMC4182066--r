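#' Flat-facet triangular shell element
#'
#' The element superposes a constant-strain triangle (CST) for membrane
#' action with a discrete Kirchhoff triangle (DKT) for plate bending, plus
#' a small artificial drilling stiffness on the rotation about the element
#' normal.  All element-level quantities are computed in a local frame with
#' the first edge along the local x axis and the element normal along local
#' z; \code{element_stiffness} returns the 18x18 operator rotated into the
#' global frame with 6 generalized displacements (3 translations, 3
#' rotations) per node.
#'
#' Internal unit system is mm-N-tonne-s, so Young's modulus enters in MPa
#' and stresses come out in MPa.
#'
#' @name shell-element
#' @keywords internal
NULL

#' Local orthonormal frame of a triangle
#'
#' @param coords 3x3 matrix, one node per row (mm).
#' @return list with \code{R} (3x3 rotation, rows = local axes; local z is
#'   the element normal implied by the winding), \code{xy} (3x2 local
#'   in-plane node coordinates) and \code{area} (mm^2).
#' @keywords internal
tri_local_frame <- function(coords) {
  e1 <- coords[2L, ] - coords[1L, ]
  e2raw <- coords[3L, ] - coords[1L, ]
  nrm <- c(
    e1[2L] * e2raw[3L] - e1[3L] * e2raw[2L],
    e1[3L] * e2raw[1L] - e1[1L] * e2raw[3L],
    e1[1L] * e2raw[2L] - e1[2L] * e2raw[1L]
  )
  a2 <- sqrt(sum(nrm^2))
  l1 <- sqrt(sum(e1^2))
  if (a2 <= .Machine$double.eps * l1^2) {
    stop("degenerate triangle (zero area)", call. = FALSE)
  }
  ex <- e1 / l1
  ez <- nrm / a2
  ey <- c(
    ez[2L] * ex[3L] - ez[3L] * ex[2L],
    ez[3L] * ex[1L] - ez[1L] * ex[3L],
    ez[1L] * ex[2L] - ez[2L] * ex[1L]
  )
  R <- rbind(ex, ey, ez)
  dimnames(R) <- NULL
  xy <- cbind(
    c(0, l1, sum(e2raw * ex)),
    c(0, 0, sum(e2raw * ey))
  )
  list(R = R, xy = xy, area = a2 / 2)
}

#' Plane-stress constitutive matrix (MPa)
#' @keywords internal
plane_stress_D <- function(E, nu) {
  E / (1 - nu^2) * rbind(
    c(1, nu, 0),
    c(nu, 1, 0),
    c(0, 0, (1 - nu) / 2)
  )
}

#' Membrane strain-displacement matrix of the CST
#'
#' Rows are (eps_x, eps_y, gamma_xy); columns follow (u1, v1, u2, v2, u3, v3)
#' in local in-plane coordinates.
#'
#' @param xy 3x2 local node coordinates.
#' @keywords internal
cst_bmatrix <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  a2 <- (x[2L] - x[1L]) * (y[3L] - y[1L]) - (x[3L] - x[1L]) * (y[2L] - y[1L])
  b <- c(y[2L] - y[3L], y[3L] - y[1L], y[1L] - y[2L])
  cc <- c(x[3L] - x[2L], x[1L] - x[3L], x[2L] - x[1L])
  B <- matrix(0, 3L, 6L)
  for (i in 1:3) {
    B[1L, 2L * i - 1L] <- b[i]
    B[2L, 2L * i] <- cc[i]
    B[3L, 2L * i - 1L] <- cc[i]
    B[3L, 2L * i] <- b[i]
  }
  B / a2
}

#' CST membrane stiffness (local, 6x6)
#' @keywords internal
cst_membrane_stiffness <- function(xy, thickness, E, nu) {
  fr_area <- abs((xy[2L, 1L] - xy[1L, 1L]) * (xy[3L, 2L] - xy[1L, 2L]) -
    (xy[3L, 1L] - xy[1L, 1L]) * (xy[2L, 2L] - xy[1L, 2L])) / 2
  B <- cst_bmatrix(xy)
  D <- plane_stress_D(E, nu)
  thickness * fr_area * crossprod(B, D %*% B)
}

# Maps from the 9 nodal dofs (w_i, thx_i, thy_i) to the rotation-field
# values (beta_x, beta_y) = (w,x, w,y) at the 3 corner and 3 mid-side nodes
# of the quadratic interpolation.  Kirchhoff conditions: at corners the
# rotations equal the nodal slopes (thx = w,y; thy = -w,x); along each edge
# the transverse deflection is the cubic Hermite of the end values, pinning
# the mid-side tangential slope, while the normal slope varies linearly.
dkt_rotation_maps <- function(xy) {
  BX <- matrix(0, 6L, 9L)
  BY <- matrix(0, 6L, 9L)
  for (i in 1:3) {
    cw <- 3L * (i - 1L)
    BX[i, cw + 3L] <- -1  # w,x = -thy
    BY[i, cw + 2L] <- 1   # w,y =  thx
  }
  edge_i <- c(2L, 3L, 1L)
  edge_j <- c(3L, 1L, 2L)
  for (k in 1:3) {
    i <- edge_i[k]; j <- edge_j[k]
    d <- xy[j, ] - xy[i, ]
    l <- sqrt(sum(d^2))
    s <- d / l
    n <- c(-s[2L], s[1L])
    ci <- 3L * (i - 1L); cj <- 3L * (j - 1L)
    # tangential slope at mid-edge from the Hermite cubic:
    #   w,s(mid) = 3 (w_j - w_i) / (2 l) - (w,s_i + w,s_j) / 4
    bs <- numeric(9L)
    bs[ci + 1L] <- -3 / (2 * l)
    bs[cj + 1L] <- 3 / (2 * l)
    # w,s at a corner = s_x * w,x + s_y * w,y = -s_x * thy + s_y * thx
    bs[ci + 2L] <- bs[ci + 2L] - s[2L] / 4
    bs[ci + 3L] <- bs[ci + 3L] + s[1L] / 4
    bs[cj + 2L] <- bs[cj + 2L] - s[2L] / 4
    bs[cj + 3L] <- bs[cj + 3L] + s[1L] / 4
    # normal slope linear along the edge
    bn <- numeric(9L)
    bn[ci + 2L] <- n[2L] / 2
    bn[ci + 3L] <- -n[1L] / 2
    bn[cj + 2L] <- n[2L] / 2
    bn[cj + 3L] <- -n[1L] / 2
    BX[3L + k, ] <- bs * s[1L] + bn * n[1L]
    BY[3L + k, ] <- bs * s[2L] + bn * n[2L]
  }
  list(BX = BX, BY = BY)
}

# quadratic shape-function derivatives at (xi, eta); node order:
# corners 1,2,3 then mid-sides on edges (2,3), (3,1), (1,2)
quad_tri_dshape <- function(xi, eta) {
  la <- 1 - xi - eta
  dN_xi <- c(1 - 4 * la, 4 * xi - 1, 0, 4 * eta, -4 * eta, 4 * (la - xi))
  dN_eta <- c(1 - 4 * la, 0, 4 * eta - 1, 4 * xi, 4 * (la - eta), -4 * xi)
  cbind(dN_xi, dN_eta)
}

#' Bending strain-displacement matrix of the DKT at a point
#'
#' Rows are the curvatures (w,xx; w,yy; 2 w,xy) of the constrained rotation
#' field; columns follow (w1, thx1, thy1, w2, thx2, thy2, w3, thx3, thy3)
#' where thx/thy are the physical rotations about the local x/y axes
#' (thx = dw/dy, thy = -dw/dx for a rigid rotation).
#'
#' @param xy 3x2 local node coordinates.
#' @param xi,eta area coordinates of the evaluation point.
#' @param maps optional precomputed \code{dkt_rotation_maps(xy)}.
#' @keywords internal
dkt_bmatrix <- function(xy, xi, eta, maps = dkt_rotation_maps(xy)) {
  x21 <- xy[2L, 1L] - xy[1L, 1L]
  y21 <- xy[2L, 2L] - xy[1L, 2L]
  x31 <- xy[3L, 1L] - xy[1L, 1L]
  y31 <- xy[3L, 2L] - xy[1L, 2L]
  a2 <- x21 * y31 - x31 * y21
  dN <- quad_tri_dshape(xi, eta)
  # betax,x etc. via the inverse Jacobian of the affine map
  bx_xi <- crossprod(dN[, 1L], maps$BX)
  bx_eta <- crossprod(dN[, 2L], maps$BX)
  by_xi <- crossprod(dN[, 1L], maps$BY)
  by_eta <- crossprod(dN[, 2L], maps$BY)
  bx_x <- (y31 * bx_xi - y21 * bx_eta) / a2
  bx_y <- (-x31 * bx_xi + x21 * bx_eta) / a2
  by_x <- (y31 * by_xi - y21 * by_eta) / a2
  by_y <- (-x31 * by_xi + x21 * by_eta) / a2
  rbind(bx_x, by_y, bx_y + by_x)
}

#' DKT plate-bending stiffness (local, 9x9)
#'
#' Exact 3-point mid-edge integration of the cubic-derived curvature field.
#' @keywords internal
dkt_bending_stiffness <- function(xy, thickness, E, nu) {
  x31 <- xy[3L, 1L] - xy[1L, 1L]
  y31 <- xy[3L, 2L] - xy[1L, 2L]
  x21 <- xy[2L, 1L] - xy[1L, 1L]
  y21 <- xy[2L, 2L] - xy[1L, 2L]
  area <- abs(x21 * y31 - x31 * y21) / 2
  Db <- thickness^3 / 12 * plane_stress_D(E, nu)
  gp <- rbind(c(0.5, 0), c(0, 0.5), c(0.5, 0.5))
  maps <- dkt_rotation_maps(xy)
  K <- matrix(0, 9L, 9L)
  for (g in 1:3) {
    B <- dkt_bmatrix(xy, gp[g, 1L], gp[g, 2L], maps)
    K <- K + crossprod(B, Db %*% B)
  }
  K * area / 3
}

#' Element stiffness of the flat shell triangle (global frame, 18x18)
#'
#' @param coords 3x3 matrix of node coordinates (mm), one node per row,
#'   wound so the right-hand normal is the element's reference normal.
#' @param thickness shell thickness (mm).
#' @param material a \code{\link{material}} object (or any list with
#'   \code{E_mpa} and \code{poisson}).
#' @param drilling_factor drilling stiffness as a fraction of the smallest
#'   diagonal bending-rotation stiffness entry.
#' @return symmetric 18x18 matrix; dof order is
#'   (ux, uy, uz, rx, ry, rz) per node, nodes in triangle order.
#' @export
element_stiffness <- function(coords, thickness, material,
                              drilling_factor = 1e-4) {
  if (thickness <= 0) stop("thickness must be positive", call. = FALSE)
  fr <- tri_local_frame(coords)
  E <- material$E_mpa
  nu <- material$poisson
  Km <- cst_membrane_stiffness(fr$xy, thickness, E, nu)
  Kb <- dkt_bending_stiffness(fr$xy, thickness, E, nu)

  Kl <- matrix(0, 18L, 18L)
  # local dof layout per node i: 6(i-1) + (u, v, w, thx, thy, thz)
  mem <- as.vector(vapply(0:2, function(i) 6L * i + c(1L, 2L), integer(2)))
  bnd <- as.vector(vapply(0:2, function(i) 6L * i + c(3L, 4L, 5L), integer(3)))
  drl <- 6L * (0:2) + 6L
  Kl[mem, mem] <- Km
  Kl[bnd, bnd] <- Kb
  # drilling penalty ties each normal-rotation dof to the in-plane rotation
  # 0.5*(v,x - u,y) of the membrane field, so it vanishes on every rigid
  # motion yet stiffens uniform drilling rotation; scaled by the membrane
  # stiffness E*t*A (a bending-based scale, proportional to t^3, collapses
  # on thin shells and leaves a spurious near-zero mechanism)
  kd <- drilling_factor * E * thickness * fr$area
  Bm <- cst_bmatrix(fr$xy)
  g <- numeric(18L)
  for (i in 1:3) {
    g[6L * (i - 1L) + 1L] <- -Bm[2L, 2L * i] / 2     # -u_i coeff of u,y
    g[6L * (i - 1L) + 2L] <- Bm[1L, 2L * i - 1L] / 2 # v_i coeff of v,x
  }
  for (i in drl) {
    e <- numeric(18L); e[i] <- 1
    d <- e - g
    Kl <- Kl + kd * tcrossprod(d)
  }

  T6 <- kronecker(diag(6L), fr$R)
  K <- crossprod(T6, Kl %*% T6)
  (K + t(K)) / 2
}
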