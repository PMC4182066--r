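#' Rectangular plate test mesh
#'
#' Structured right-triangle mesh of an a x b rectangle in the z = 0 plane,
#' mainly for solver verification (plate benchmarks, patch tests).
#' Winding gives +z element normals.
#'
#' @param a,b side lengths (mm) along x and y.
#' @param nx,ny number of subdivisions along x and y.
#' @param thickness shell thickness (mm).
#' @param region element label.
#' @return a \code{\link{shell_mesh}} with no fixed or load nodes set.
#' @export
plate_mesh <- function(a, b, nx, ny, thickness, region = "plate") {
  xs <- seq(0, a, length.out = nx + 1L)
  ys <- seq(0, b, length.out = ny + 1L)
  nodes <- cbind(
    rep(xs, times = ny + 1L),
    rep(ys, each = nx + 1L),
    0
  )
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  tris <- matrix(0L, 2L * nx * ny, 3L)
  e <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      n00 <- nid(i, j); n10 <- nid(i + 1L, j)
      n01 <- nid(i, j + 1L); n11 <- nid(i + 1L, j + 1L)
      tris[e + 1L, ] <- c(n00, n10, n11)
      tris[e + 2L, ] <- c(n00, n11, n01)
      e <- e + 2L
    }
  }
  shell_mesh(nodes, tris, thickness, region)
}

# node selections on the plate rectangle boundary
plate_boundary_nodes <- function(mesh, a, b, tol = 1e-9) {
  x <- mesh$nodes[, 1L]; y <- mesh$nodes[, 2L]
  which(x < tol | x > a - tol | y < tol | y > b - tol)
}

#' Navier series center deflection of a simply supported plate
#'
#' Classical double-sine series for a uniformly loaded, simply supported
#' rectangular Kirchhoff plate; used as the independent oracle for the
#' plate-bending benchmark.
#'
#' @param q uniform pressure (N/mm^2).
#' @param a,b plate sides (mm).
#' @param D flexural rigidity E t^3 / (12 (1 - nu^2)) (N mm).
#' @param nterms odd series terms per direction.
#' @return center deflection (mm).
#' @export
navier_plate_center_deflection <- function(q, a, b, D, nterms = 99) {
  mm <- seq(1, nterms, by = 2)
  w <- 0
  for (m in mm) {
    for (n in mm) {
      w <- w + sin(m * pi / 2) * sin(n * pi / 2) /
        (m * n * ((m / a)^2 + (n / b)^2)^2)
    }
  }
  16 * q * w / (pi^6 * D)
}

#' Fundamental frequency of a simply supported plate
#'
#' Analytic Kirchhoff result omega_11 = pi^2 (1/a^2 + 1/b^2) sqrt(D / (rho t)).
#'
#' @inheritParams navier_plate_center_deflection
#' @param rho_t mass per unit area (tonne/mm^2).
#' @return angular frequency (rad/s).
#' @export
plate_fundamental_frequency <- function(a, b, D, rho_t) {
  pi^2 * (1 / a^2 + 1 / b^2) * sqrt(D / rho_t)
}

# assemble a simply supported bending-only plate system: w = 0 on the
# boundary, in-plane translations and drilling fixed everywhere (membrane
# and bending decouple on a flat plate)
ss_plate_system <- function(mesh, a, b, mat) {
  sys <- assemble(mesh, mat)
  nnode <- nrow(mesh$nodes)
  bnd <- plate_boundary_nodes(mesh, a, b)
  fix <- c(
    as.vector(vapply(seq_len(nnode), function(n) {
      6L * (n - 1L) + c(1L, 2L, 6L)
    }, integer(3))),
    6L * (bnd - 1L) + 3L
  )
  sys$constrained_dofs <- sort(unique(fix))
  sys$free_dofs <- setdiff(seq_len(sys$ndof), sys$constrained_dofs)
  sys
}

# consistent nodal forces for uniform transverse pressure q on the plate
plate_pressure_load <- function(mesh, q) {
  ge <- mesh_element_geometry(mesh)
  nnode <- nrow(mesh$nodes)
  fz <- numeric(nnode)
  for (k in 1:3) {
    fz <- fz + tapply_add(q * ge$area / 3, mesh$triangles[, k], nnode)
  }
  f <- numeric(6L * nnode)
  f[seq(3L, by = 6L, length.out = nnode)] <- fz
  f
}

# smallest nonzero generalized eigenfrequency by inverse power iteration
lowest_frequency <- function(system, tol = 1e-10, maxit = 500L) {
  free <- system$free_dofs
  Kff <- system$K[free, free]
  m <- system$M[free]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
  set.seed(0L)
  x <- rnorm(length(free))
  x <- x / sqrt(sum(m * x^2))
  lam <- Inf
  for (it in seq_len(maxit)) {
    y <- as.numeric(Matrix::solve(ch, m * x))
    lam_new <- sum(x * m * x) / sum(x * m * y) # omega^2 estimate
    x <- y / sqrt(sum(m * y^2))
    if (it > 3L && abs(lam_new - lam) <= tol * abs(lam_new)) {
      lam <- lam_new
      break
    }
    lam <- lam_new
  }
  sqrt(lam)
}

#' Membrane patch test
#'
#' Prescribes an arbitrary linear in-plane displacement field on the
#' boundary of a distorted flat patch, solves for the interior, and
#' reports the worst relative deviation of any element's membrane strain
#' from the field's constant strain.
#'
#' @param nx,ny patch subdivisions.
#' @param distort interior-node perturbation as a fraction of the cell
#'   size.
#' @param gradient 2x2 displacement-gradient matrix defining the linear
#'   field.
#' @param mat a \code{\link{material}}.
#' @return max relative strain deviation (dimensionless).
#' @export
membrane_patch_test <- function(nx = 4L, ny = 3L, distort = 0.2,
                                gradient = rbind(c(3e-3, 1e-3),
                                                 c(-2e-3, 5e-3)),
                                mat = material()) {
  a <- 20; b <- 15
  mesh <- plate_mesh(a, b, nx, ny, 1)
  bnd <- plate_boundary_nodes(mesh, a, b)
  interior <- setdiff(seq_len(nrow(mesh$nodes)), bnd)
  set.seed(7L)
  mesh$nodes[interior, 1:2] <- mesh$nodes[interior, 1:2] +
    matrix(runif(2L * length(interior), -distort, distort), ncol = 2L) *
      rep(c(a / nx, b / ny), each = length(interior))
  sys <- assemble(mesh, mat)
  nnode <- nrow(mesh$nodes)
  # constrain the out-of-plane dofs everywhere (bending decouples on a
  # flat patch) and prescribe boundary membrane dofs; drilling rotations
  # stay free so they can settle at the field's in-plane rotation
  u <- numeric(sys$ndof)
  presc <- integer()
  for (n in seq_len(nnode)) {
    presc <- c(presc, 6L * (n - 1L) + 3:5)
  }
  for (n in bnd) {
    d <- gradient %*% mesh$nodes[n, 1:2]
    u[6L * (n - 1L) + 1L] <- d[1L]
    u[6L * (n - 1L) + 2L] <- d[2L]
    presc <- c(presc, 6L * (n - 1L) + 1:2)
  }
  presc <- sort(unique(presc))
  free <- setdiff(seq_len(sys$ndof), presc)
  f <- -as.numeric(sys$K[free, presc] %*% u[presc])
  u[free] <- as.numeric(Matrix::solve(sys$K[free, free], f))
  strain_ref <- c(
    gradient[1L, 1L], gradient[2L, 2L], gradient[1L, 2L] + gradient[2L, 1L]
  )
  worst <- 0
  for (e in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[e, ]
    fr <- tri_local_frame(mesh$nodes[tri, , drop = FALSE])
    edofs <- as.vector(vapply(tri, function(n) 6L * (n - 1L) + 1:6, integer(6)))
    uloc <- kronecker(diag(6L), fr$R) %*% u[edofs]
    mem <- as.vector(vapply(0:2, function(i) 6L * i + c(1L, 2L), integer(2)))
    eps <- as.numeric(cst_bmatrix(fr$xy) %*% uloc[mem])
    # rotate the strain tensor from the element frame back to global axes
    El <- fr$R[1:2, 1:2]
    Et <- t(El) %*% rbind(
      c(eps[1L], eps[3L] / 2), c(eps[3L] / 2, eps[2L])
    ) %*% El
    eps_g <- c(Et[1L, 1L], Et[2L, 2L], 2 * Et[1L, 2L])
    worst <- max(
      worst, max(abs(eps_g - strain_ref)) / max(abs(strain_ref))
    )
  }
  worst
}

#' Single-dof oscillator system
#'
#' A minimal \code{global_system} with one free translational dof carrying
#' stiffness \code{k} (N/mm) and mass \code{m} (tonne), for integrator
#' verification against the harmonic-oscillator closed form.
#'
#' @param k stiffness (N/mm).
#' @param m mass (tonne).
#' @param mat material (only its Rayleigh coefficients are used).
#' @return a \code{global_system}.
#' @export
sdof_system <- function(k = 1, m = 1, mat = material()) {
  mesh <- shell_mesh(
    nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    triangles = matrix(c(1L, 2L, 3L), 1L), thickness = 1
  )
  K <- Matrix::sparseMatrix(
    i = 1L, j = 1L, x = k, dims = c(18L, 18L), symmetric = TRUE
  )
  structure(
    list(
      K = K, M = c(m, rep(1, 17L)), ndof = 18L,
      constrained_dofs = 2:18, free_dofs = 1L,
      mesh = mesh, material = mat
    ),
    class = "global_system"
  )
}

# a load case exerting no force (profile shape is irrelevant)
zero_load_case <- function() {
  load_case(1L, c(1, 0, 0), 0, cbind(c(0, 1e-3, 2e-3), c(0, 1, 0)))
}

#' Oscillation period from a displacement trace
#'
#' Mean spacing of interpolated downward zero crossings.
#'
#' @param times snapshot times (s).
#' @param trace displacement samples.
#' @return period (s), or NA if fewer than two crossings.
#' @export
trace_period <- function(times, trace) {
  crossings <- c()
  for (i in seq_len(length(trace) - 1L)) {
    if (trace[i] > 0 && trace[i + 1L] <= 0) {
      frac <- trace[i] / (trace[i] - trace[i + 1L])
      crossings <- c(crossings, times[i] + frac * (times[i + 1L] - times[i]))
    }
  }
  if (length(crossings) < 2L) return(NA_real_)
  mean(diff(crossings))
}

#' Analytic verification benchmark suite
#'
#' Runs the solver-correctness benchmarks: membrane patch test, simply
#' supported plate deflection against the Navier series, plate fundamental
#' frequency against the analytic Kirchhoff result, single-dof oscillator
#' period, undamped energy balance on the default orbit run, and the
#' central-difference vs Newmark probe-trace agreement on that run.
#' Failures are reported in the table, not raised.
#'
#' @param include_orbit if FALSE, the two orbit-run benchmarks (the slow
#'   ones) are skipped.
#' @param orbit_cache optional precomputed list with \code{mesh},
#'   \code{system}, \code{case} to reuse.
#' @return data.frame with columns benchmark, value, reference, metric,
#'   tolerance, pass.
#' @export
run_benchmarks <- function(include_orbit = TRUE, orbit_cache = NULL) {
  rows <- list()
  add <- function(benchmark, value, reference, metric, tolerance) {
    rows[[length(rows) + 1L]] <<- data.frame(
      benchmark = benchmark, value = value, reference = reference,
      metric = metric, tolerance = tolerance,
      pass = is.finite(metric) && metric <= tolerance
    )
  }

  mat <- material()

  dev <- membrane_patch_test()
  add("membrane patch test", dev, 0, dev, 1e-8)

  a <- 100; t <- 1; q <- 0.01
  D <- mat$E_mpa * t^3 / (12 * (1 - mat$poisson^2))
  mesh <- plate_mesh(a, a, 32L, 32L, t)
  sysp <- ss_plate_system(mesh, a, a, mat)
  u <- static_solve(sysp, plate_pressure_load(mesh, q))
  ic <- which.min((mesh$nodes[, 1L] - a / 2)^2 + (mesh$nodes[, 2L] - a / 2)^2)
  wc <- u[6L * (ic - 1L) + 3L]
  wref <- navier_plate_center_deflection(q, a, a, D)
  add("plate center deflection", wc, wref, abs(wc / wref - 1), 0.02)

  mesh16 <- plate_mesh(a, a, 16L, 16L, t)
  sysf <- ss_plate_system(mesh16, a, a, mat)
  om <- lowest_frequency(sysf)
  om_ref <- plate_fundamental_frequency(a, a, D, mat$rho * t)
  add("plate fundamental frequency", om, om_ref, abs(om / om_ref - 1), 0.03)

  sdof <- sdof_system(1, 1)
  dt <- stable_dt(sdof) / 20
  hist <- integrate_transient(
    sdof, zero_load_case(),
    time_config(dt = dt, t_end = 6 * pi, snapshot_interval = dt),
    initial = list(u = c(1, rep(0, 17L)))
  )
  Tn <- trace_period(hist$times, hist$U[1L, ])
  add("oscillator period", Tn, 2 * pi, abs(Tn / (2 * pi) - 1), 0.005)

  if (include_orbit) {
    if (is.null(orbit_cache)) {
      omesh <- generate_orbit(orbit_params())
      osys <- assemble(omesh, mat)
      ocase <- default_strike_load(omesh)
    } else {
      omesh <- orbit_cache$mesh
      osys <- orbit_cache$system
      ocase <- orbit_cache$case
    }
    oh <- integrate_transient(osys, ocase, time_config())
    en <- oh$energy
    imb <- max(abs(
      en$external_work - (en$kinetic + en$strain + en$dissipated)
    )) / max(en$external_work)
    add("undamped energy balance", imb, 0, imb, 0.01)

    dts <- stable_dt(osys) / 2
    pA <- omesh$probe_A
    hcd <- integrate_transient(osys, ocase, time_config(dt = dts))
    hnm <- integrate_transient(
      osys, ocase, time_config("newmark_average_acceleration", dt = dts)
    )
    fcd <- signed_wall_displacement(hcd, omesh)
    fnm <- signed_wall_displacement(hnm, omesh)
    diffp <- max(abs(fcd$s[pA, ] - fnm$s[pA, ])) / max(abs(fcd$s[pA, ]))
    add("central difference vs Newmark", diffp, 0, diffp, 0.05)
  }

  do.call(rbind, rows)
}
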